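# Screening-economics scenario (plain-text key-value; GBP throughout).
# Lines map 1:1 onto econ_scenario() arguments.
cohort_size = 1000
scan_cost = 3000
prevalence = 0.33
annual_cost_active = 39141
annual_cost_remitted = 15086
delay_years = 4
clozapine_response = 0.5
# The next three have NO published values; review against your local costs
# (clozapine drug + mandatory monitoring service; neutropenia management;
# any additional harm assigned to unnecessary clozapine exposure).
clozapine_annual_cost = 2500
neutropenia_incidence = 0.03
neutropenia_cost = 5000
false_positive_penalty = 0
sensitivity = 0.5
specificity = 0.95
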