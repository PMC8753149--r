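quantity,value,units
region_area_km2,194811,km2
pes_assumed_area_km2,52683,km2
national_pa_area_km2,314052,km2
proposed_pa_area_km2,8610,km2
baseline_pct_connectivity_in_pa,27.1,percent
newpa_scenario_pct,41.1,percent
pes_scenario_pct,32.1,percent
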