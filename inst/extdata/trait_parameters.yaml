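# Genetic architecture of the ten-trait dam-line panel used throughout the
# package, together with the economic values of the four breeding goals.
#
# Variances are on the trait-unit-squared scale; heritability is the published
# rounded value used as a cross-check (sa2/sp2 must reproduce it at 2 dp).
# sex_recording drives the phenotype-availability mask:
#   both_sexes  - recorded on male and female selection candidates
#   female_only - recorded on female candidates only
#   cull_only   - recorded at slaughter on candidates culled without selection
traits:
  - {code: GR30,  unit: g/day,       sex_recording: both_sexes,  heritability: 0.29, additive_variance: 185.0,   phenotypic_variance: 637.931,  environmental_variance: 452.931}
  - {code: GR100, unit: g/day,       sex_recording: both_sexes,  heritability: 0.33, additive_variance: 1536.0,  phenotypic_variance: 4654.545, environmental_variance: 3118.545}
  - {code: LMP,   unit: "%",         sex_recording: cull_only,   heritability: 0.44, additive_variance: 0.275,   phenotypic_variance: 0.625,    environmental_variance: 0.350}
  - {code: ST,    unit: points,      sex_recording: both_sexes,  heritability: 0.17, additive_variance: 0.100,   phenotypic_variance: 0.588,    environmental_variance: 0.488}
  - {code: FE,    unit: FE/kg gain,  sex_recording: both_sexes,  heritability: 0.32, additive_variance: 0.006,   phenotypic_variance: 0.019,    environmental_variance: 0.013}
  - {code: LP5,   unit: N/litter,    sex_recording: female_only, heritability: 0.06, additive_variance: 0.900,   phenotypic_variance: 15.000,   environmental_variance: 14.100}
  - {code: SL,    unit: kg,          sex_recording: cull_only,   heritability: 0.30, additive_variance: 0.600,   phenotypic_variance: 2.000,    environmental_variance: 1.400}
  - {code: LG,    unit: "%",         sex_recording: female_only, heritability: 0.17, additive_variance: 0.028,   phenotypic_variance: 0.165,    environmental_variance: 0.137}
  - {code: PM,    unit: "%",         sex_recording: female_only, heritability: 0.04, additive_variance: 0.120,   phenotypic_variance: 3.000,    environmental_variance: 2.880}
  - {code: NFT,   unit: number,      sex_recording: female_only, heritability: 0.31, additive_variance: 0.035,   phenotypic_variance: 0.113,    environmental_variance: 0.078}

# Non-zero off-diagonal genetic correlations (upper triangle); omitted pairs are 0.
genetic_correlations:
  - [GR30,  GR100,  0.46]
  - [GR30,  LMP,   -0.04]
  - [GR30,  FE,    -0.20]
  - [GR30,  LP5,   -0.05]
  - [GR30,  NFT,    0.19]
  - [GR100, LMP,   -0.20]
  - [GR100, FE,    -0.30]
  - [GR100, LP5,   -0.15]
  - [GR100, LG,    -0.25]
  - [GR100, PM,     0.05]
  - [LMP,   FE,    -0.34]
  - [LMP,   LP5,    0.05]
  - [LMP,   LG,    -0.11]
  - [LMP,   PM,     0.05]
  - [ST,    LP5,   -0.10]
  - [ST,    LG,     0.13]
  - [ST,    PM,    -0.15]
  - [LP5,   LG,     0.26]
  - [LP5,   PM,    -0.40]
  - [LP5,   NFT,    0.13]

# Non-zero off-diagonal phenotypic correlations (lower triangle); omitted pairs are 0.
phenotypic_correlations:
  - [GR30,  GR100,  0.06]
  - [GR30,  LMP,    0.05]
  - [GR30,  FE,    -0.04]
  - [GR100, LMP,    0.04]
  - [GR100, FE,    -0.53]
  - [GR100, LG,     0.09]
  - [LMP,   FE,    -0.07]
  - [ST,    LG,     0.05]
  - [LP5,   PM,     0.20]

# Economic values in EUR per trait unit, in the trait order above.
economic_values:
  CBG:     {GR30: 0.015, GR100: 0.017, LMP: 1.293, ST: 1.667, FE: -19.600, LP5: 2.613, SL: -0.680, LG: 11.333, PM: 0.0,    NFT: 0.0}
  curOBG:  {GR30: 0.012, GR100: 0.029, LMP: 1.533, ST: 1.667, FE: -29.333, LP5: 0.693, SL: -1.747, LG: 11.333, PM: 0.0,    NFT: 0.0}
  altOBG:  {GR30: 0.068, GR100: 0.019, LMP: 1.898, ST: 4.723, FE: -31.412, LP5: 1.228, SL: -0.283, LG: 3.177,  PM: 0.0,    NFT: 0.0}
  altOBG+: {GR30: 0.113, GR100: 0.013, LMP: 1.029, ST: 0.0,   FE: -23.659, LP5: 1.631, SL: 0.0,    LG: 0.0,    PM: -2.232, NFT: 3.753}
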