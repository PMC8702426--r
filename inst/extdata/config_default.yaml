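# Base-case model inputs: 2021 US dollars (6.4769 CNY/USD), per 3-week
# cycle unless noted. Ranges are +/-20% for costs and +/-10% for
# utilities and adverse-event risks; Gamma distributions for costs and
# Beta for probabilities/utilities in the probabilistic analysis; the
# discount rate is fixed in the PSA and varied 0-0.08 deterministically.

drugs:
  camrelizumab:  {base: 452.08,  low: 361.66,  high: 542.50}
  carboplatin:   {base: 17.65,   low: 14.12,   high: 21.18}
  pemetrexed:    {base: 1103.30, low: 882.64,  high: 1323.96}
  docetaxel:     {base: 94.10,   low: 75.28,   high: 112.92}
  gefitinib:     {base: 161.47,  low: 129.18,  high: 193.76}
  bevacizumab:   {base: 1788.42, low: 1430.73, high: 2146.10}
  nivolumab:     {base: 4283.44, low: 3426.75, high: 5140.13}

other_costs:
  supportive:    {base: 338.00,  low: 270.40,  high: 405.60}   # per cycle
  followup:      {base: 85.71,   low: 68.57,   high: 102.85}   # per cycle
  palliative:    {base: 2464.50, low: 1971.60, high: 2957.40}  # per death

ae_costs:  # grade 3-4 management, one-off
  neutropenia:      {base: 175.37, low: 140.30, high: 210.44}
  anemia:           {base: 101.02, low: 80.82,  high: 121.22}
  thrombocytopenia: {base: 603.79, low: 483.03, high: 724.55}

ae_risks:
  experimental:
    neutropenia:      {base: 0.38, low: 0.34, high: 0.42}
    anemia:           {base: 0.19, low: 0.17, high: 0.21}
    thrombocytopenia: {base: 0.17, low: 0.15, high: 0.19}
  control:
    neutropenia:      {base: 0.30, low: 0.27, high: 0.33}
    anemia:           {base: 0.11, low: 0.10, high: 0.12}
    thrombocytopenia: {base: 0.12, low: 0.11, high: 0.13}

utilities:
  pfs: {base: 0.81, low: 0.73, high: 0.90}   # stable disease
  pd:  {base: 0.58, low: 0.52, high: 0.64}   # progressed disease

disutilities:
  neutropenia:      {base: 0.20, low: 0.18, high: 0.22}
  anemia:           {base: 0.07, low: 0.07, high: 0.08}
  thrombocytopenia: {base: 0.11, low: 0.10, high: 0.12}

discount: {base: 0.05, low: 0.00, high: 0.08}

model:
  cycle_length_weeks: 3
  horizon_cycles: 520        # 30 years: operational lifetime horizon
  wtp: 31500                 # $/QALY, triple per-capita GDP
  stop_threshold: 1.0e-4

strategies:
  experimental:
    name: camrelizumab_chemotherapy
    induction_drugs: [camrelizumab, carboplatin, pemetrexed]
    maintenance_drugs: [camrelizumab, pemetrexed]
    induction_cycles: 4
    max_treatment_cycles: 35   # camrelizumab capped at 2 years
    subsequent_fraction: 0.58
    # INVENTED weights: second-line mix after the camrelizumab arm (no
    # PD-1 rechallenge); the trial's supplementary regimen mix is not
    # public.
    subsequent_mix: {docetaxel: 0.40, gefitinib: 0.10, bevacizumab: 0.30, nivolumab: 0.20}
    subsequent_max_cycles: 6
    tot_ratio: 0.85            # median time-on-treatment / median PFS
  control:
    name: chemotherapy
    induction_drugs: [carboplatin, pemetrexed]
    maintenance_drugs: [pemetrexed]
    induction_cycles: 4
    max_treatment_cycles: .inf
    subsequent_fraction: 0.70
    # INVENTED weights: 46% of progressors crossed over to camrelizumab
    # monotherapy (0.657 of the treated fraction); remainder split.
    subsequent_mix: {camrelizumab: 0.657, docetaxel: 0.143, gefitinib: 0.10, bevacizumab: 0.10}
    subsequent_max_cycles: 6
    tot_ratio: 0.85

scenario:
  # Crossover-adjusted scenario: the control-arm OS is replaced by its
  # RPSFT counterfactual and its second line contains no PD-1/PD-L1
  # antibodies.
  control_subsequent_mix: {docetaxel: 0.60, gefitinib: 0.20, bevacizumab: 0.20}

trial:
  # Calibrated synthetic-trial scenario (see trial_scenario()); scales
  # and shapes in weeks.
  n_per_arm: 205
  pfs:
    experimental: {scale: 61.307, shape: 1.6556}
    control:      {scale: 45.031, shape: 1.6556}
  os:
    experimental: {scale: 69.224, shape: 0.80}
    control:      {scale: 27.850, shape: 0.80}
  censor_range_weeks: [208, 260]
  switch_prob: 0.46
  psi: -1.20
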