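item,category,unit,value,source_label
price_year,meta,label,2020/21,price year for all packaged costs
setup_per_participant,intervention,GBP per participant,68,calibrated to the published set-up component
sachet,intervention,GBP per sachet,1.45147540803706,calibrated so the discounted 5-year intervention total equals 1691
practitioner_minute,intervention,GBP per minute,0.66666666666666663,PSSRU-style band D nurse time (packaged default; editable)
visit_default_minutes,intervention,minutes,30,assumed average appointment duration (config knob)
contact_gp,primary_care,GBP per contact,41,PSSRU 2020/21-style GP contact (packaged default; editable)
contact_nurse,primary_care,GBP per contact,18.5,PSSRU 2020/21-style practice nurse contact (packaged default; editable)
contact_healthcare_assistant,primary_care,GBP per contact,14,PSSRU 2020/21-style HCA contact (packaged default; editable)
contact_other,primary_care,GBP per contact,45,other community contact (packaged default; editable)
contact_secondary_care,secondary_care,GBP per attendance,211,NHS reference-cost-style outpatient attendance (packaged default; editable)
hospital_episode_elective,hospital,GBP per episode,3847,NHS reference-cost-style elective inpatient episode (packaged default; editable)
hospital_episode_emergency,hospital,GBP per episode,2035,NHS reference-cost-style non-elective episode (packaged default; editable)
hospital_episode_day_case,hospital,GBP per episode,829,NHS reference-cost-style day case (packaged default; editable)
excess_bed_day,hospital,GBP per day,346,national tariff-style excess bed-day (packaged default; editable)
trim_point_elective,hospital,days,7,national tariff-style trim point (packaged default; editable)
trim_point_emergency,hospital,days,5,national tariff-style trim point (packaged default; editable)
trim_point_day_case,hospital,days,0,day cases carry no excess bed-days
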