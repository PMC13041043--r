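# Station rosters and water-mass pairings for the source/sink estimator.
# Shelf stations provide the marine endmember of each pair; fjord stations
# the "diluted" side.  The synthetic study generated by the package uses
# the same rosters, so this file works for both.
Kongsfjorden:
  shelf: [V10, V12, V14]
  fjord: [Kb0, Kb1, Kb2, Kb3, Kb4, Kb5]
  pairs:
    - {year: 2016, shelf_wm: AW, fjord_wm: IW}
    - {year: 2016, shelf_wm: AW, fjord_wm: SW}
    - {year: 2016, shelf_wm: AW, fjord_wm: AW}
    - {year: 2017, shelf_wm: AW, fjord_wm: IW}
    - {year: 2017, shelf_wm: AW, fjord_wm: SW}
    - {year: 2017, shelf_wm: AW, fjord_wm: AW}
Rijpfjorden:
  shelf: [R4, R5, R6, R6-b, R7, R7-b]
  fjord: [R1, R2, R3]
  pairs:
    - {year: 2016, shelf_wm: ArW, fjord_wm: ArW}
    - {year: 2016, shelf_wm: ArW, fjord_wm: SW}
    - {year: 2017, shelf_wm: ArW, fjord_wm: ArW}
    - {year: 2017, shelf_wm: ArW, fjord_wm: SW}
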