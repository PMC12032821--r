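# Senegal parameter set with Cote d'Ivoire substandard proportions
country: "Senegal (Cote d'Ivoire medicine quality)"
percent: false
demography:
  total_population: 17316449        # persons
  crude_birth_rate: 33              # births per 1,000 persons per year
  mmr: 261                          # maternal deaths per 100,000 live births
  life_expectancy_female: 69        # years
  mean_age_maternal_death: 29.5     # years
  gdp_per_capita: 1598.70           # USD per year
  discount_rate: 0.03               # per year, productivity-loss discounting
  pph_share_of_maternal_deaths: 0.30
delivery:
  urban_fraction: 0.30
  weights:                          # survey columns; renormalized on load
    urban:
      public_hospital_vaginal: 0.10
      public_hospital_cesarean: 0.04
      phc_vaginal: 0.75
      private_hospital_vaginal: 0.06
      private_hospital_cesarean: 0.01
      home: 0.05
    rural:
      public_hospital_vaginal: 0.03
      public_hospital_cesarean: 0.02
      phc_vaginal: 0.62
      private_hospital_vaginal: 0.01
      private_hospital_cesarean: 0.00
      home: 0.31
utilization:
  facility:
    oxytocin: 0.34
    oxytocin_misoprostol: 0.66
  home:
    none: 1.0
quality:                            # proportion of product that is substandard
  oxytocin:
    public: 0.54
    private: 0.54
  misoprostol:
    public: 0.04
    private: 0.04
    home: 0.38
risk_ratios:                        # substandard vs quality-assured product
  pph: 1.29                         # blood loss >= 500 ml
  severe: 1.26                      # blood loss >= 1,000 ml
risks:                              # quality-assured prophylaxis risks
  oxytocin:
    vaginal:  {p500: 0.12, p500_range: [0.10, 0.15], p1000: 0.03, p1000_range: [0.02, 0.04]}
    cesarean: {p500: 0.60, p500_range: [0.57, 0.63], p1000: 0.13, p1000_range: [0.13, 0.14]}
  oxytocin_misoprostol:
    vaginal:  {p500: 0.09, p500_range: [0.07, 0.11], p1000: 0.03, p1000_range: [0.02, 0.03]}
    cesarean: {p500: 0.42, p500_range: [0.35, 0.52], p1000: 0.12, p1000_range: [0.09, 0.13]}
  misoprostol:
    vaginal:  {p500: 0.13, p500_range: [0.12, 0.15], p1000: 0.04, p1000_range: [0.03, 0.04]}
  carbetocin:
    vaginal:  {p500: 0.09, p500_range: [0.08, 0.10], p1000: 0.03, p1000_range: [0.02, 0.03]}
    cesarean: {p500: 0.44, p500_range: [0.39, 0.48], p1000: 0.12, p1000_range: [0.10, 0.13]}
  none:
    vaginal:  {p500: 0.24, p500_range: [0.19, 0.29], p1000: 0.05, p1000_range: [0.04, 0.06]}
care:
  additional_treatment:             # proportion of PPH cases, by product quality
    quality: 0.58
    substandard: 0.73
  transfusion:
    quality: 0.19
    substandard: 0.38
  surgery_severe_vaginal: 0.20      # postpartum surgery among severe vaginal PPH
  referral_severe: 0.18             # referral of severe PPH from home and PHC
  diagnosed: 0.40                   # share of facility PPH cases diagnosed
costs:                              # USD per delivery, by severity tier
  public_hospital:
    vaginal:  {no_pph: 20.44, mild: 30.97, severe: 43.16, severe_surgery: 66.76}
    cesarean: {no_pph: 53.84, mild: 69.94, severe: 77.06, severe_surgery: 100.66}
  phc:
    vaginal:  {no_pph: 20.44, mild: 24.97, severe: 31.40}
  private_hospital:
    vaginal:  {no_pph: 213.73, mild: 224.91, severe: 289.83, severe_surgery: 1065.83}
    cesarean: {no_pph: 788.36, mild: 806.03, severe: 861.83, severe_surgery: 1605.83}
psa:
  n_draws: 1000
  default_rel_halfwidth: 0.25       # +/-25% relative 95% interval for unranged inputs
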