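# Base-case inputs for the adjuvant-osimertinib cost-effectiveness model.
# All currency is inflation-adjusted US dollars; all times are years.
horizon_years: 10
cycles_per_year: 12                 # monthly cycles
discount_rate_costs: 0.03           # annual
discount_rate_qalys: 0.05           # annual
threshold: 195000                   # willingness to pay per QALY (3x US GDP per capita)
os_hazard_ratio: 0.95               # assumed post-progression mortality HR, osimertinib arm
background_mortality_annual: 0.012  # non-disease mortality, US male aged 63
drug_discount_fraction: 0.0         # price reduction applied to all osimertinib cost lines
adjuvant_drug_years: 3              # osimertinib in NED, per protocol
pd_drug_years: 2                    # osimertinib re-treatment window after progression
structure: stratified               # NED-exit structure: stratified | competing

costs:
  egfr_test_once: 324.58            # one-time; at start (osimertinib arm) or progression (placebo)
  osimertinib_annual: 222196        # per year, adjuvant, up to 3 years or until progression
  ned_annual_yr1_3: 1078.76         # NED health care, first 3 years
  ned_annual_yr4_5: 539.38          # NED health care, years 4-5
  ned_annual_after5: 296.69         # NED health care, after year 5
  pd_diagnosis_once: 7202.88        # one-time work-up at progression
  osimertinib_pd_annual: 222196     # per year at progression, first 2 years
  pd_annual: 1186.76                # PD health care, annual
  cns_pos_once: 43598.83            # average lifetime CNS+ treatment/toxicity, one-time
  cns_mri_annual: 1482.56           # surveillance MRI while in CNS+ PD
  end_of_life_once: 78571.06        # palliative / end-of-life

utilities:
  ned_placebo: 0.830
  ned_osimertinib: 0.812
  pd_cns_neg: 0.71
  pd_cns_pos: 0.55

# Disease-free survival fits (log-normal, log-time scale, years) and the
# post-progression survival fit (gamma, shape/rate per year; mean 3.32 y).
dfs_fits:
  placebo_cns_pos:      {family: lognormal, meanlog: 1.94, sdlog: 1.22}
  placebo_cns_neg:      {family: lognormal, meanlog: 1.11, sdlog: 1.44}
  osimertinib_cns_pos:  {family: lognormal, meanlog: 2.66, sdlog: 0.91}
  osimertinib_cns_neg:  {family: lognormal, meanlog: 2.19, sdlog: 1.13}
pd_death_fit: {family: gamma, shape: 1.86, rate: 0.56}

# Disease-free survival event splits (recurrences / total events) at the
# trial interim analysis; fractions are computed, never hard-coded.
event_splits:
  placebo_cns_pos:      {recurrences: 33, events: 39}
  osimertinib_cns_pos:  {recurrences: 4,  events: 6}
  placebo_cns_neg:      {recurrences: 118, events: 120}
  osimertinib_cns_neg:  {recurrences: 31, events: 31}

# Grade >= 3 adverse events: probability-weighted one-time cost and QALY
# decrement. "ned" rows trigger at adjuvant treatment start (osimertinib
# arm); "pd" rows at progression (both arms receive osimertinib at PD);
# "cns" rows at CNS+ progression (their costs are already folded into
# cns_pos_once, hence cost 0 here).
adverse_events:
  - {name: diarrhea,               stage: ned, probability: 0.023, disutility: -0.32, cost: 159.68}
  - {name: rash_stomatitis,        stage: ned, probability: 0.018, disutility: -0.15, cost: 169.97}
  - {name: decreased_appetite,     stage: ned, probability: 0.005, disutility: -0.39, cost: 38.25}
  - {name: pneumonia_sepsis,       stage: ned, probability: 0.015, disutility: -0.50, cost: 42928.16}
  - {name: diarrhea,               stage: pd,  probability: 0.025, disutility: -0.32, cost: 159.68}
  - {name: rash_itching_dry_skin,  stage: pd,  probability: 0.018, disutility: -0.15, cost: 169.97}
  - {name: decreased_appetite,     stage: pd,  probability: 0.011, disutility: -0.39, cost: 38.25}
  - {name: pneumonia_sepsis,       stage: pd,  probability: 0.047, disutility: -0.50, cost: 42928.16}
  - {name: pneumonitis_respiratory, stage: pd, probability: 0.050, disutility: -0.40, cost: 16584.44}
  - {name: neurocognitive_defects, stage: cns, probability: 0.10,  disutility: -0.35, cost: 0}
  - {name: radionecrosis,          stage: cns, probability: 0.01,  disutility: -0.50, cost: 0}
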