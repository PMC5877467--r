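event,controlled,free_living
lighter_press_release,193,356
cigarettes_from_lighter,185,337
cigarettes_self_report,185,319
h2m_from_imu,2519,17639
breaths_rip,14232,99985
breaths_bioimpedance,13629,98546
h2m_proximity,2819,19388
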