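arm,category,error,count
llm,cat1_screen_recommended,missed_failed_to_offer,5
llm,cat3_normal_followup,unnecessary_short_interval,5
human_closed,cat1_screen_recommended,missed_long_interval,3
human_closed,cat1_screen_recommended,missed_failed_to_offer,10
human_closed,cat2_screen_not_recommended,unnecessary_did_not_require,14
human_closed,cat2_screen_not_recommended,missed_long_interval,3
human_closed,cat3_normal_followup,unnecessary_short_interval,8
human_closed,cat3_normal_followup,unnecessary_did_not_require,8
human_closed,cat3_normal_followup,missed_failed_to_offer,3
human_closed,cat4_elevated_psa,missed_long_interval,20
human_closed,cat4_elevated_psa,missed_failed_to_offer,1
human_closed,cat5_other,unnecessary_short_interval,3
human_closed,cat5_other,unnecessary_did_not_require,10
human_open,cat1_screen_recommended,missed_long_interval,1
human_open,cat1_screen_recommended,missed_failed_to_offer,10
human_open,cat2_screen_not_recommended,unnecessary_did_not_require,10
human_open,cat3_normal_followup,unnecessary_short_interval,7
human_open,cat3_normal_followup,unnecessary_did_not_require,7
human_open,cat3_normal_followup,missed_long_interval,1
human_open,cat4_elevated_psa,unnecessary_short_interval,1
human_open,cat4_elevated_psa,missed_long_interval,12
human_open,cat5_other,unnecessary_short_interval,2
human_open,cat5_other,unnecessary_did_not_require,6
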