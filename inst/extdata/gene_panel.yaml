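# Nitrogen-cycle marker gene panel and single-copy reference genes.
processes:
  nifH: nitrogen_fixation
  amoA: nitrification
  amoB: nitrification
  hao: nitrification
  nosZ: denitrification
  nirK: denitrification
  norB: denitrification
  hdh: anammox
  napA: nitrate_nitrite_reduction
  nirD: nitrate_nitrite_reduction
  narB: assimilatory_nitrate_reduction
  nasA: assimilatory_nitrate_reduction
reference: [recA, gyrB, rpoB]
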