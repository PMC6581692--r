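# Default simulation configuration: the single source of truth for every
# tunable parameter. User configuration files (YAML or JSON) are merged on
# top of this file key-by-key; `scenarios`, when supplied by the user,
# replaces the default list wholesale.
#
# Units: distances km, money USD, coordinates decimal degrees (lat, lon).
# Coefficient blocks carry a point value (`coef`) and a standard error
# (`se`) used for parameter-uncertainty draws across replicate runs.

cohort_size: 20000            # women per replicate cohort
n_runs: 200                   # replicate runs per scenario
choice_set_radius_km: 100     # road-distance radius of a woman's choice set
catastrophic_threshold: 0.10  # out-of-pocket spend > this fraction of yearly expenditure
mean_yearly_expenditure_usd: 137
master_seed: 20190611
deterministic_choice: false   # true = each woman takes her most likely facility

population:
  bbox: {lat_min: -17.1, lat_max: -9.4, lon_min: 32.7, lon_max: 35.9}
  urban_centres:
    - {name: lilongwe, lat: -13.98, lon: 33.78, weight: 0.5, sd_deg: 0.10}
    - {name: blantyre, lat: -15.79, lon: 35.01, weight: 0.5, sd_deg: 0.10}
  urban_share: 0.16
  # log-odds shift toward poorer quintiles per km from the nearest urban
  # centre (centred at the cohort mean distance); 0 switches the joint
  # wealth-location model off.
  wealth_distance_gradient: 0.008
  wealth_quintile_marginals: [0.2, 0.2, 0.2, 0.2, 0.2]
  covariates:
    literacy_prob: 0.61
    education_probs: [0.25, 0.45, 0.20, 0.10]   # ordinal levels 0..3
    parity_mean: 2.6                            # truncated Poisson, 0..10
    age_mean: 26.0
    age_sd: 7.0
    age_min: 15.0
    age_max: 49.0
    married_prob: 0.80
    anc_visits_mean: 3.5                        # truncated Poisson, 0..12
    multiple_gestation_prob: 0.02
    risky_delivery_prob: 0.15
    predicted_cs_need_prob: 0.05
  expenditure:
    # Per-quintile yearly consumption means (USD). They are rescaled at
    # sampling time so that the marginal-weighted mean equals
    # mean_yearly_expenditure_usd exactly.
    quintile_means: [55, 85, 115, 160, 270]
    gamma_shape: 4.0                            # Inf = degenerate at the mean

facilities:
  n_facilities: 540
  n_readiness_items: 10
  type_probs:
    central_hospital: 0.008
    district_hospital: 0.052
    rural_community_hospital: 0.070
    other_hospital: 0.080
    health_centre: 0.660
    clinic: 0.090
    maternity: 0.040
  urban_share: 0.30            # facilities sited near an urban centre
  # readiness ~ logistic(base[type] + urban_gain * (1 - d/d_ref) + noise)
  readiness_base:
    central_hospital: 1.6
    district_hospital: 0.9
    rural_community_hospital: 0.3
    other_hospital: 0.5
    health_centre: -0.3
    clinic: -0.8
    maternity: -0.6
  readiness_urban_gain: 1.2
  readiness_noise_sd: 0.5
  readiness_ref_distance_km: 250
  cemonc_prob:                 # probability a facility can perform caesareans
    central_hospital: 1.0
    district_hospital: 1.0
    rural_community_hospital: 0.50
    other_hospital: 0.60
    health_centre: 0.0
    clinic: 0.0
    maternity: 0.0
  bemonc_mean:                 # mean basic emergency signal functions / 3 months
    central_hospital: 9.0
    district_hospital: 7.0
    rural_community_hospital: 5.0
    other_hospital: 5.0
    health_centre: 3.0
    clinic: 1.5
    maternity: 2.5
  management_probs:            # public / ngo / private by type
    central_hospital: [1.00, 0.00, 0.00]
    district_hospital: [1.00, 0.00, 0.00]
    rural_community_hospital: [0.60, 0.30, 0.10]
    other_hospital: [0.00, 0.55, 0.45]
    health_centre: [0.75, 0.18, 0.07]
    clinic: [0.40, 0.25, 0.35]
    maternity: [0.50, 0.30, 0.20]
  fee_prob: {public: 0.05, ngo: 0.55, private: 0.95}

network:
  n_nodes: 800
  urban_share: 0.30
  knn: 3                       # extra nearest-neighbour edges beyond a spanning tree
  detour_min: 1.10             # road length / straight-line length bounds
  detour_max: 1.40
  island:                      # disconnected component (lake islands)
    enabled: true
    lat: -12.06
    lon: 34.73
    n_nodes: 6
    radius_deg: 0.06
    population_share: 0.01     # share of women placed on the island

choice_model:
  n_classes: 2
  # Class-membership multinomial logit; reference class is class 1
  # (distance- and fee-sensitive). One coefficient block per non-reference
  # class, on woman-level covariates.
  membership:
    class2:
      coef: {intercept: -1.60, wealth_quintile: 0.25, literacy: 0.30,
             parity: -0.10, anc_any: 0.20, risky_delivery: 0.30,
             predicted_cs_need: 0.40}
      se:   {intercept: 0.15, wealth_quintile: 0.04, literacy: 0.08,
             parity: 0.03, anc_any: 0.08, risky_delivery: 0.10,
             predicted_cs_need: 0.12}
  # Class-conditional utility coefficients (conditional logit); facility
  # type dummies are relative to health_centre.
  utility:
    class1:
      coef: {distance_km: -0.18, charges_fees: -2.00, readiness_score: 0.60,
             ftype_central_hospital: 0.80, ftype_district_hospital: 1.00,
             ftype_rural_community_hospital: 0.40, ftype_other_hospital: -0.20,
             ftype_clinic: -0.40, ftype_maternity: -0.50}
      se:   {distance_km: 0.012, charges_fees: 0.15, readiness_score: 0.10,
             ftype_central_hospital: 0.10, ftype_district_hospital: 0.08,
             ftype_rural_community_hospital: 0.08, ftype_other_hospital: 0.08,
             ftype_clinic: 0.10, ftype_maternity: 0.12}
    class2:
      coef: {distance_km: -0.050, charges_fees: -0.40, readiness_score: 2.80,
             ftype_central_hospital: 2.20, ftype_district_hospital: 1.50,
             ftype_rural_community_hospital: 0.50, ftype_other_hospital: 0.60,
             ftype_clinic: -0.30, ftype_maternity: -0.40}
      se:   {distance_km: 0.005, charges_fees: 0.10, readiness_score: 0.20,
             ftype_central_hospital: 0.18, ftype_district_hospital: 0.10,
             ftype_rural_community_hospital: 0.10, ftype_other_hospital: 0.10,
             ftype_clinic: 0.10, ftype_maternity: 0.12}

outcome_model:
  neonatal_mortality_target_per_1000: 23   # status-quo calibration anchor
  mortality:
    # logistic risk of neonatal death; intercept calibrated so the default
    # status-quo simulation sits near the national rate of 23 per 1000
    intercept: -3.34
    risky_delivery: 1.00
    multiple_gestation: 0.70
    readiness_score: -1.20
    cemonc_capable: -0.40
    caesarean: -0.60
  caesarean:
    p_need: 0.85          # P(caesarean | predicted need, capable facility)
    p_background: 0.12    # P(caesarean | no predicted need, capable facility)

cost_model:
  facility_fee_usd:       # charged only when charges_fees is true
    central_hospital: 15.0
    district_hospital: 10.0
    rural_community_hospital: 8.0
    other_hospital: 25.0
    health_centre: 5.0
    clinic: 8.0
    maternity: 6.0
  nonfee_cost_usd:        # supplies and sundries paid regardless of fees
    central_hospital: 2.5
    district_hospital: 2.5
    rural_community_hospital: 2.0
    other_hospital: 2.5
    health_centre: 1.5
    clinic: 1.5
    maternity: 1.5
  transport_cost_usd_per_km: 0.04
  round_trip_factor: 2    # women travel to the facility and back

scenarios:
  - {name: status_quo, restriction: none}
  - {name: scenario1_cemonc, restriction: cemonc_only}
  - {name: scenario2_cemonc_upgrade, restriction: cemonc_only,
     n_upgrades: 20, upgrade_target: cemonc}
  - {name: scenario3_bemonc, restriction: bemonc5_only}
  - {name: scenario4_bemonc_upgrade, restriction: bemonc5_only,
     n_upgrades: 30, upgrade_target: bemonc5}
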