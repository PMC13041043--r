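# File formats

All tables are UTF-8 delimited text: comma-separated for `.csv`, otherwise
tab-separated. Decimal point only; missing values are empty cells. Column
order is free; extra columns are preserved.

## CTD table (`ctd`, CSV/TSV)

One row per (station, depth).

| column | type | units / notes |
|---|---|---|
| station_id | text | e.g. `Kb1`, `V10` |
| region | text | transect / fjord name |
| year | integer | sampling year |
| depth_m | numeric | metres, >= 0 |
| temp_c | numeric | degrees Celsius |
| sal | numeric | salinity (dimensionless) |
| sigma_theta | numeric, optional | kg m^-3; computed from (sal, temp_c) when absent |
| water_mass | text, optional | written by `classify` |

## Nutrient table (`nutrients`, CSV/TSV)

One row per bottle sample.
Required: `station_id`, `region`, `year`, `depth_m`.
Optional, all numeric, mmol m^-3 (chl_a mg m^-3): `ammonium`,
`nitrate_nitrite`, `nitrite`, `phosphate`, `silicic_acid`, `chl_a`;
`sal` (bottle salinity — merged from the CTD table by
(station, region, year, depth) when absent).

## Taxa tables (TSV)

- counts: first column `asv_id`, remaining columns one per sample, cells
  are non-negative integer read counts.
- taxonomy: `asv_id`, `domain` (required), `phylum`, `class`, `order`,
  `family`, `genus` (optional, empty = unassigned).
- sample metadata: `sample_id`, `region`, `year`, `depth_m`, `water_mass`.

## Gene count table (`gene_counts`, TSV)

One row per (sample, gene, contig): `sample_id`, `gene_symbol`,
`contig_id` (optional), `mapped_reads` (>= 0), `gene_length_bp` (> 0).

## Envelope configuration (YAML)

```yaml
sigma_threshold: 27.92          # AW/TAW fallback density threshold
precedence: [WCW, ArW, LW, SW, IW, TAW, AW]
envelopes:
  AW: {t_min: 3.0, s_min: 34.9, sigma_max: 27.92}
  ArW: {t_min: -1.5, t_max: 1.0, s_min: 34.3, s_max: 34.8}
  # t_min/t_max/s_min/s_max/sigma_max all optional (unbounded if absent);
  # per-edge closedness flags: t_min_closed, t_max_closed, s_min_closed,
  # s_max_closed (default: lower bounds closed, upper bounds open)
```

## Station roles (YAML)

```yaml
Kongsfjorden:
  shelf: [V10, V12, V14]
  fjord: [Kb0, Kb1, Kb2, Kb3, Kb4, Kb5]
  pairs:
    - {year: 2016, shelf_wm: AW, fjord_wm: IW}
```

## Gene panel (YAML)

```yaml
processes:
  amoA: nitrification
  # gene -> process, one entry per panel gene
reference: [recA, gyrB, rpoB]   # single-copy normalization genes
```
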