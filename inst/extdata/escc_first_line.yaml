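# Default model configuration: first-line pembrolizumab + cisplatin/5-FU
# vs chemotherapy alone in advanced ESCC (PD-L1 CPS >= 10), Chinese payer
# perspective, 2021 USD.
#
# Each parameter: value (base case), optionally low/high (sensitivity range)
# and psa (sampling family: gamma | beta | beta_abs | beta_range).

model:
  cycle_days: 21          # q3w dosing interval
  horizon_years: 10
  half_cycle: true        # half-cycle correction on accruals
  intervention: pembro_chemo
  comparator: chemo

parameters:
  # --- log-logistic survival laws, S(t) = 1/(1 + scale * t^shape), t months
  os_shape_pembro:  {value: 1.59}
  os_scale_pembro:  {value: 0.015}
  os_shape_chemo:   {value: 1.70}
  os_scale_chemo:   {value: 0.022}
  pfs_shape_pembro: {value: 1.75}
  pfs_scale_pembro: {value: 0.029}
  pfs_shape_chemo:  {value: 2.27}
  pfs_scale_chemo:  {value: 0.028}

  # --- drug unit costs, USD per mg
  cost_pembrolizumab_mg: {value: 25.98,   low: 12.99,   high: 25.98,  psa: gamma}
  cost_fluorouracil_mg:  {value: 0.03956, low: 0.03297, high: 0.04239, psa: gamma}
  cost_cisplatin_mg:     {value: 0.1036,  low: 0.1036,  high: 0.1463, psa: gamma}
  cost_docetaxel_mg:     {value: 1.77,    low: 0.26,    high: 14.95,  psa: gamma}
  cost_irinotecan_mg:    {value: 1.64,    low: 0.88,    high: 4.65,   psa: gamma}

  # --- grade >= 3 adverse-event management costs, USD per event
  cost_ae_anemia:      {value: 73.68, low: 55.27, high: 92.11,  psa: gamma}
  cost_ae_neutropenia: {value: 67.56, low: 55.27, high: 200.66, psa: gamma}

  # --- grade >= 3 adverse-event incidences (proportions)
  inc_anemia_pembro:      {value: 0.12, low: 0.096, high: 0.144, psa: beta}
  inc_neutropenia_pembro: {value: 0.23, low: 0.184, high: 0.276, psa: beta}
  inc_anemia_chemo:       {value: 0.15, low: 0.12,  high: 0.18,  psa: beta}
  inc_neutropenia_chemo:  {value: 0.17, low: 0.136, high: 0.204, psa: beta}

  # --- health-state utilities and adverse-event disutilities
  utility_pfd:            {value: 0.741,  low: 0.593,  high: 0.889,  psa: beta}
  utility_pd:             {value: 0.581,  low: 0.465,  high: 0.697,  psa: beta}
  disutility_anemia:      {value: -0.074, low: -0.110, high: -0.037, psa: beta_abs}
  disutility_neutropenia: {value: -0.090, low: -0.120, high: -0.059, psa: beta_abs}

  # --- other economics
  followup_cost_per_cycle: {value: 51.5, low: 45.0, high: 58.4, psa: beta_range}
  bsa_m2:                  {value: 1.72, low: 1.5,  high: 1.9,  psa: beta_range}
  annual_discount:         {value: 0.05, low: 0.0,  high: 0.08, psa: beta_range}
  wtp_per_qaly:            {value: 37663.26}   # 3x 2021 Chinese GDP per capita

  # --- treatment rules
  max_cycles_pembrolizumab: {value: 35, low: 1, high: 35, integer: true}
  max_cycles_first_line:    {value: 35, low: 1, high: 35, integer: true}
  max_cycles_cisplatin:     {value: 6,  low: 1, high: 6,  integer: true}
  second_line_docetaxel_weight: {value: 0.5, low: 0.4, high: 0.6}
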