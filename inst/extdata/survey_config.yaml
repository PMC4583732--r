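n_subsidized: 344.0
n_private: 471.0
caretaker_mean:
  subsidized: 2.3
  private: 3.3
z: 0.1
catastrophic_target: 0.43
component_dists:
- stratum: subsidized
  column: cost_medical_subsidy
  median: 500.0
  q1: 106.25
  q3: 1462.5
  p_zero: .na.real
- stratum: subsidized
  column: cost_medical_oop
  median: 56.5
  q1: 0.0
  q3: 500.0
  p_zero: .na.real
- stratum: subsidized
  column: cost_travel_home_oop
  median: 81.5
  q1: 8.0
  q3: 437.25
  p_zero: .na.real
- stratum: subsidized
  column: cost_airfare_subsidy
  median: 336.0
  q1: 200.0
  q3: 419.25
  p_zero: .na.real
- stratum: subsidized
  column: cost_airfare_oop
  median: 400.0
  q1: 336.0
  q3: 672.0
  p_zero: .na.real
- stratum: subsidized
  column: cost_travel_dest_oop
  median: 91.0
  q1: 35.0
  q3: 200.0
  p_zero: .na.real
- stratum: subsidized
  column: cost_entertainment_oop
  median: 34.5
  q1: 0.0
  q3: 200.0
  p_zero: .na.real
- stratum: subsidized
  column: cost_lodging_oop
  median: 150.0
  q1: 67.0
  q3: 300.0
  p_zero: .na.real
- stratum: subsidized
  column: cost_food_oop
  median: 140.0
  q1: 56.0
  q3: 300.0
  p_zero: .na.real
- stratum: subsidized
  column: cost_visa_oop
  median: 0.0
  q1: 0.0
  q3: 0.0
  p_zero: .na.real
- stratum: subsidized
  column: cost_fx_oop
  median: 0.0
  q1: 0.0
  q3: 0.0
  p_zero: .na.real
- stratum: subsidized
  column: cost_other_oop
  median: 0.0
  q1: 0.0
  q3: 0.0
  p_zero: .na.real
- stratum: private
  column: cost_medical_subsidy
  median: 0.0
  q1: 0.0
  q3: 0.0
  p_zero: 1.0
- stratum: private
  column: cost_airfare_subsidy
  median: 0.0
  q1: 0.0
  q3: 0.0
  p_zero: 1.0
- stratum: private
  column: cost_medical_oop
  median: 300.0
  q1: 147.5
  q3: 720.5
  p_zero: .na.real
- stratum: private
  column: cost_travel_home_oop
  median: 180.0
  q1: 60.0
  q3: 450.0
  p_zero: .na.real
- stratum: private
  column: cost_airfare_oop
  median: 750.0
  q1: 520.0
  q3: 1100.0
  p_zero: .na.real
- stratum: private
  column: cost_travel_dest_oop
  median: 120.0
  q1: 45.0
  q3: 250.0
  p_zero: .na.real
- stratum: private
  column: cost_entertainment_oop
  median: 142.0
  q1: 0.0
  q3: 400.0
  p_zero: .na.real
- stratum: private
  column: cost_lodging_oop
  median: 127.0
  q1: 47.0
  q3: 300.0
  p_zero: .na.real
- stratum: private
  column: cost_food_oop
  median: 100.0
  q1: 46.0
  q3: 210.0
  p_zero: .na.real
- stratum: private
  column: cost_visa_oop
  median: 0.0
  q1: 0.0
  q3: 0.0
  p_zero: .na.real
- stratum: private
  column: cost_fx_oop
  median: 0.0
  q1: 0.0
  q3: 0.0
  p_zero: .na.real
- stratum: private
  column: cost_other_oop
  median: 0.0
  q1: 0.0
  q3: 0.0
  p_zero: .na.real
budget:
  share_lo:
  - 1.2
  - 25.0
  share_hi:
  - 3.5
  - 8.5
  total_median: 1000.0
  total_q1: 600.0
  total_q3: 1700.0
  food_frac_shape:
  - 8.0
  - 5.0
income:
  median: 1000.0
  q1: 600.0
  q3: 1800.0
los:
  median: 15.0
  q1: 9.0
  q3: 24.0
productivity:
  p_zero_hours: 0.6
  hours_min: 2.0
  hours_max: 8.0
  income_day:
    median: 33.0
    q1: 16.0
    q3: 66.0
visits_rate: 0.3
categoricals:
  sex_probs:
    subsidized:
      female: 0.491279069767442
      male: 0.508720930232558
    private:
      female: 0.664543524416136
      male: 0.335456475583864
  age_probs:
    subsidized:
      0-9: 0.15406976744186
      10-19: 0.069767441860465
      20-29: 0.087209302325581
      30-59: 0.473837209302326
      60-85: 0.215116279069767
    private:
      0-9: 0.097664543524416
      10-19: 0.072186836518047
      20-29: 0.13588110403397
      30-59: 0.564755838641189
      60-85: 0.129511677282378
  region_probs:
    subsidized:
      North: 0.25
      Central: 0.552325581395349
      South: 0.197674418604651
    private:
      North: 0.337579617834395
      Central: 0.373673036093418
      South: 0.288747346072187
  occupation_probs:
    subsidized:
      civil_servant: 0.151162790697674
      private_sector: 0.101744186046512
      own_business: 0.223837209302326
      not_employed: 0.395348837209302
      other: 0.127906976744186
    private:
      civil_servant: 0.252653927813163
      private_sector: 0.089171974522293
      own_business: 0.186836518046709
      not_employed: 0.331210191082803
      other: 0.140127388535032
  hh_size_probs:
    subsidized:
      small: 0.584302325581395
      medium: 0.290697674418605
      large: 0.125
    private:
      small: 0.588110403397028
      medium: 0.316348195329087
      large: 0.095541401273885
  destination_probs:
    subsidized:
      India: 0.694767441860465
      Sri Lanka: 0.305232558139535
      Thailand: 0.0
      Italy: 0.0
    private:
      India: 0.64755838641189
      Sri Lanka: 0.339702760084926
      Thailand: 0.010615711252654
      Italy: 0.002123142250531
  chapter_probs:
    I00: 0.100613496932515
    G00: 0.084662576687117
    M00: 0.079754601226994
    N00: 0.076073619631902
    H00: 0.062576687116564
    C00: 0.062576687116564
    R00: 0.060122699386503
    S00: 0.052760736196319
    K00: 0.042944785276074
    E00: 0.042944785276074
    Z00: 0.207361963190184
    J00: 0.030674846625767
    F00: 0.024539877300613
    L00: 0.012269938650307
    O00: 0.012269938650307
    Q00: 0.011042944785276
    H60: 0.009815950920245
    A00: 0.009815950920245
    D50: 0.008588957055215
    P00: 0.004907975460123
    V01: 0.003680981595092
    U00: 0.0
seed: 20130601.0
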