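# Guideline-standard cut points; every field maps to an hdp_thresholds()
# argument and may be overridden per site.
sbp_cut: 140          # mmHg, inclusive
dbp_cut: 90           # mmHg, inclusive
ch_boundary: 140      # days; "before 20 weeks" means < 140
eo_lo_cut: 238        # days; early onset iff disorder onset < 34 weeks
pu_single_grade: 3    # dipstick rank 3 = "2+", qualifies at one visit
pu_repeat_grade: 2    # dipstick rank 2 = "1+"
pu_repeat_count: 2    # ... at this many distinct visits
bp_repeat_count: 1    # qualifying visits required for hypertension
platelet_low: 100     # 10^3/uL, strict <
creatinine_high: 1.1  # mg/dL, strict >
transaminase_uln_multiplier: 2
ast_uln: 30           # U/L
alt_uln: 30           # U/L
lfd_percentile: 10
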