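# Default analyte panel: 30 quantified targets (16 uremic toxins, 14 bile
# acids) plus the two isotope-labelled internal standards, one per ESI mode.
# calibration_range is the matrix-matched standard range in uM (extract scale).
# Analytes with excluded: true are panel members that are never quantified
# (on-column accumulation); they must carry a non-empty exclusion reason.
intstd_nominal:
  negative: 10.0   # p-CS-d7 spike, uM in every vial
  positive: 1.0    # GDCA-d6 spike, uM in every vial
matrices: [plasma, feces]
dilution_schemes:
  plasma: [1, 2, 50]   # neat, 1:1, 1:49
  feces:  [1, 2, 10]   # neat, 1:1, 1:9
analytes:
  - {id: p-CS-d7, name: p-Cresol sulfate-d7, class: uremic_toxin, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false, internal_standard_flag: true}
  - {id: GDCA-d6, name: Glycodeoxycholic acid-d6, class: secondary_bile_acid, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false, internal_standard_flag: true}
  - {id: p-CS, name: p-Cresol sulfate, class: uremic_toxin, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: PS, name: Phenyl sulfate, class: uremic_toxin, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: IS, name: Indoxyl sulfate, class: uremic_toxin, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: MPS, name: 2-Methoxyphenyl sulfate, class: uremic_toxin, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: DG, name: Diethyl glutarate, class: uremic_toxin, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: APN, name: 2-Aminophenol, class: uremic_toxin, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: HA, name: Hippuric acid, class: uremic_toxin, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: CMG, name: Cinnamoylglycine, class: uremic_toxin, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: PAG, name: Phenylacetylglycine, class: uremic_toxin, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: HHA, name: m-Hydroxyhippuric acid, class: uremic_toxin, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: PAGlu, name: Phenylacetylglutamine, class: uremic_toxin, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: TMAO, name: Trimethylamine N-oxide, class: uremic_toxin, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: GB, name: 4-Guanidinobutyric acid, class: uremic_toxin, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: true,
     exclusion_reason: accumulates on the analytical column}
  - {id: NAG, name: N-Acetylglutamine, class: uremic_toxin, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: ImP, name: Imidazole propionate, class: uremic_toxin, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: DMG, name: Dimethylglycine, class: uremic_toxin, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: CA, name: Cholic acid, class: primary_bile_acid, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: CDCA, name: Chenodeoxycholic acid, class: primary_bile_acid, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: true,
     exclusion_reason: accumulates on the analytical column}
  - {id: GCA, name: Glycocholic acid, class: primary_bile_acid, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: true,
     exclusion_reason: accumulates on the analytical column}
  - {id: TCA, name: Taurocholic acid, class: primary_bile_acid, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: LCA, name: Lithocholic acid, class: secondary_bile_acid, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: DCA, name: Deoxycholic acid, class: secondary_bile_acid, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: UDCA, name: Ursodeoxycholic acid, class: secondary_bile_acid, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: omega-MCA, name: omega-Muricholic acid, class: secondary_bile_acid, esi_mode: negative,
     internal_standard: p-CS-d7, conjugate_group: none,
     calibration_range: [0.005, 20], excluded: false}
  - {id: TCDCA, name: Taurochenodeoxycholic acid, class: secondary_bile_acid, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: taurine_conjugates,
     calibration_range: [0.005, 20], excluded: false}
  - {id: TDCA, name: Taurodeoxycholic acid, class: secondary_bile_acid, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: taurine_conjugates,
     calibration_range: [0.005, 20], excluded: false}
  - {id: TUDCA, name: Tauroursodeoxycholic acid, class: secondary_bile_acid, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: taurine_conjugates,
     calibration_range: [0.005, 20], excluded: false}
  - {id: GCDCA, name: Glycochenodeoxycholic acid, class: secondary_bile_acid, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: glycine_conjugates,
     calibration_range: [0.005, 20], excluded: false}
  - {id: GDCA, name: Glycodeoxycholic acid, class: secondary_bile_acid, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: glycine_conjugates,
     calibration_range: [0.005, 20], excluded: false}
  - {id: GUDCA, name: Glycoursodeoxycholic acid, class: secondary_bile_acid, esi_mode: positive,
     internal_standard: GDCA-d6, conjugate_group: glycine_conjugates,
     calibration_range: [0.005, 20], excluded: false}
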