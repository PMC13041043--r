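# Water-mass envelopes for Svalbard-type fjord transects.
# Bounds after Cottier et al. (2005), J. Geophys. Res. 110, C12005, Table 1.
# Lower bounds are closed and upper bounds open unless *_closed flags say
# otherwise.  sigma_max applies only to the Atlantic-derived classes; the
# global sigma_threshold drives the AW/TAW fallback rule for records inside
# an Atlantic T-S box but denser than the threshold.
sigma_threshold: 27.92
precedence: [WCW, ArW, LW, SW, IW, TAW, AW]
envelopes:
  SW:                       # Surface Water: warm, fresh summer layer
    t_min: 1.0
    s_max: 34.0
  IW:                       # Intermediate Water
    t_min: 1.0
    s_min: 34.0
    s_max: 34.7
  AW:                       # Atlantic Water
    t_min: 3.0
    s_min: 34.9
    sigma_max: 27.92
  TAW:                      # Transformed Atlantic Water
    t_min: 1.0
    t_max: 3.0
    s_min: 34.7
    sigma_max: 27.92
  ArW:                      # Arctic Water
    t_min: -1.5
    t_max: 1.0
    s_min: 34.3
    s_max: 34.8
  LW:                       # Local Water
    t_min: -0.5
    t_max: 1.0
    s_min: 34.3
  WCW:                      # Winter-cooled Water
    t_max: -0.5
    s_min: 34.4
    s_max: 35.0
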