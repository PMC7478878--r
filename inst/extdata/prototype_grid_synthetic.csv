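patient_id,follow_up_days,day_index,question_id,response,reason
P01,7,1,DYSPNEA,no,
P01,7,1,WEIGHT,68.0,
P01,7,1,MEDICATION,yes,
P01,7,1,FATIGUE,no,
P01,7,2,DYSPNEA,no,
P01,7,2,WEIGHT,68.0,
P01,7,2,MEDICATION,yes,
P01,7,2,FATIGUE,no,
P01,7,3,DYSPNEA,no,
P01,7,3,WEIGHT,68.0,
P01,7,3,MEDICATION,yes,
P01,7,3,FATIGUE,no,
P01,7,4,DYSPNEA,yes,
P01,7,4,WEIGHT,68.0,
P01,7,4,MEDICATION,yes,
P01,7,4,FATIGUE,no,
P01,7,5,DYSPNEA,yes,
P01,7,5,WEIGHT,68.0,
P01,7,5,MEDICATION,yes,
P01,7,5,FATIGUE,no,
P01,7,6,DYSPNEA,no,
P01,7,6,WEIGHT,68.0,
P01,7,6,MEDICATION,yes,
P01,7,6,FATIGUE,no,
P01,7,7,DYSPNEA,no,
P01,7,7,WEIGHT,68.0,
P01,7,7,MEDICATION,yes,
P01,7,7,FATIGUE,no,
P02,7,1,DYSPNEA,no,
P02,7,1,WEIGHT,72.5,
P02,7,1,MEDICATION,yes,
P02,7,1,FATIGUE,no,
P02,7,2,DYSPNEA,no,
P02,7,2,WEIGHT,72.5,
P02,7,2,MEDICATION,yes,
P02,7,2,FATIGUE,no,
P02,7,3,DYSPNEA,no,
P02,7,3,WEIGHT,72.5,
P02,7,3,MEDICATION,yes,
P02,7,3,FATIGUE,no,
P02,7,4,DYSPNEA,yes,
P02,7,4,WEIGHT,72.5,
P02,7,4,MEDICATION,yes,
P02,7,4,FATIGUE,no,
P02,7,5,DYSPNEA,yes,
P02,7,5,WEIGHT,72.5,
P02,7,5,MEDICATION,yes,
P02,7,5,FATIGUE,no,
P02,7,6,DYSPNEA,no,
P02,7,6,WEIGHT,72.5,
P02,7,6,MEDICATION,yes,
P02,7,6,FATIGUE,no,
P02,7,7,DYSPNEA,no,
P02,7,7,WEIGHT,72.5,
P02,7,7,MEDICATION,yes,
P02,7,7,FATIGUE,no,
P03,7,1,DYSPNEA,no,
P03,7,1,WEIGHT,80.0,
P03,7,1,MEDICATION,yes,
P03,7,1,FATIGUE,no,
P03,7,2,DYSPNEA,no,
P03,7,2,WEIGHT,80.0,
P03,7,2,MEDICATION,yes,
P03,7,2,FATIGUE,no,
P03,7,3,DYSPNEA,no,
P03,7,3,WEIGHT,80.0,
P03,7,3,MEDICATION,yes,
P03,7,3,FATIGUE,no,
P03,7,4,DYSPNEA,yes,
P03,7,4,WEIGHT,80.0,
P03,7,4,MEDICATION,yes,
P03,7,4,FATIGUE,no,
P03,7,5,DYSPNEA,yes,
P03,7,5,WEIGHT,80.0,
P03,7,5,MEDICATION,yes,
P03,7,5,FATIGUE,no,
P03,7,6,DYSPNEA,no,
P03,7,6,WEIGHT,80.0,
P03,7,6,MEDICATION,yes,
P03,7,6,FATIGUE,no,
P03,7,7,DYSPNEA,no,
P03,7,7,WEIGHT,80.0,
P03,7,7,MEDICATION,yes,
P03,7,7,FATIGUE,no,
P04,7,1,DYSPNEA,no,
P04,7,1,WEIGHT,75.5,
P04,7,1,MEDICATION,yes,
P04,7,1,FATIGUE,no,
P04,7,2,DYSPNEA,no,
P04,7,2,WEIGHT,75.5,
P04,7,2,MEDICATION,yes,
P04,7,2,FATIGUE,no,
P04,7,3,DYSPNEA,no,
P04,7,3,WEIGHT,75.5,
P04,7,3,MEDICATION,yes,
P04,7,3,FATIGUE,no,
P04,7,4,DYSPNEA,no,
P04,7,4,WEIGHT,75.5,
P04,7,4,MEDICATION,yes,
P04,7,4,FATIGUE,yes,
P04,7,5,DYSPNEA,no,
P04,7,5,WEIGHT,75.5,
P04,7,5,MEDICATION,yes,
P04,7,5,FATIGUE,yes,
P04,7,6,DYSPNEA,no,
P04,7,6,WEIGHT,75.5,
P04,7,6,MEDICATION,yes,
P04,7,6,FATIGUE,no,
P04,7,7,DYSPNEA,no,
P04,7,7,WEIGHT,75.5,
P04,7,7,MEDICATION,yes,
P04,7,7,FATIGUE,no,
P05,7,1,DYSPNEA,no,
P05,7,1,WEIGHT,66.0,
P05,7,1,MEDICATION,yes,
P05,7,1,FATIGUE,no,
P05,7,2,DYSPNEA,no,
P05,7,2,WEIGHT,66.0,
P05,7,2,MEDICATION,yes,
P05,7,2,FATIGUE,no,
P05,7,3,DYSPNEA,no,
P05,7,3,WEIGHT,66.0,
P05,7,3,MEDICATION,yes,
P05,7,3,FATIGUE,no,
P05,7,4,DYSPNEA,no,
P05,7,4,WEIGHT,66.0,
P05,7,4,MEDICATION,yes,
P05,7,4,FATIGUE,yes,
P05,7,5,DYSPNEA,no,
P05,7,5,WEIGHT,66.0,
P05,7,5,MEDICATION,yes,
P05,7,5,FATIGUE,yes,
P05,7,6,DYSPNEA,no,
P05,7,6,WEIGHT,66.0,
P05,7,6,MEDICATION,yes,
P05,7,6,FATIGUE,no,
P05,7,7,DYSPNEA,no,
P05,7,7,WEIGHT,66.0,
P05,7,7,MEDICATION,yes,
P05,7,7,FATIGUE,no,
P06,7,1,DYSPNEA,no,
P06,7,1,WEIGHT,84.0,
P06,7,1,MEDICATION,yes,
P06,7,1,FATIGUE,no,
P06,7,2,DYSPNEA,no,
P06,7,2,WEIGHT,84.0,
P06,7,2,MEDICATION,yes,
P06,7,2,FATIGUE,no,
P06,7,3,DYSPNEA,no,
P06,7,3,WEIGHT,84.0,
P06,7,3,MEDICATION,yes,
P06,7,3,FATIGUE,no,
P06,7,4,DYSPNEA,no,
P06,7,4,WEIGHT,84.0,
P06,7,4,MEDICATION,yes,
P06,7,4,FATIGUE,yes,
P06,7,5,DYSPNEA,no,
P06,7,5,WEIGHT,84.0,
P06,7,5,MEDICATION,yes,
P06,7,5,FATIGUE,yes,
P06,7,6,DYSPNEA,no,
P06,7,6,WEIGHT,84.0,
P06,7,6,MEDICATION,yes,
P06,7,6,FATIGUE,no,
P06,7,7,DYSPNEA,no,
P06,7,7,WEIGHT,84.0,
P06,7,7,MEDICATION,yes,
P06,7,7,FATIGUE,no,
P07,7,1,DYSPNEA,no,
P07,7,1,WEIGHT,70.5,
P07,7,1,MEDICATION,yes,
P07,7,1,FATIGUE,no,
P07,7,2,DYSPNEA,no,
P07,7,2,WEIGHT,70.5,
P07,7,2,MEDICATION,yes,
P07,7,2,FATIGUE,no,
P07,7,3,DYSPNEA,no,
P07,7,3,WEIGHT,70.5,
P07,7,3,MEDICATION,yes,
P07,7,3,FATIGUE,no,
P07,7,4,DYSPNEA,no,
P07,7,4,WEIGHT,70.5,
P07,7,4,MEDICATION,yes,
P07,7,4,FATIGUE,yes,
P07,7,5,DYSPNEA,no,
P07,7,5,WEIGHT,70.5,
P07,7,5,MEDICATION,yes,
P07,7,5,FATIGUE,yes,
P07,7,6,DYSPNEA,no,
P07,7,6,WEIGHT,70.5,
P07,7,6,MEDICATION,yes,
P07,7,6,FATIGUE,no,
P07,7,7,DYSPNEA,no,
P07,7,7,WEIGHT,70.5,
P07,7,7,MEDICATION,yes,
P07,7,7,FATIGUE,no,
P08,7,1,DYSPNEA,no,
P08,7,1,WEIGHT,78.0,
P08,7,1,MEDICATION,yes,
P08,7,1,FATIGUE,no,
P08,7,2,DYSPNEA,,POWER_OUTAGE
P08,7,2,WEIGHT,,POWER_OUTAGE
P08,7,2,MEDICATION,,POWER_OUTAGE
P08,7,2,FATIGUE,no,
P08,7,3,DYSPNEA,,POWER_OUTAGE
P08,7,3,WEIGHT,78.0,
P08,7,3,MEDICATION,yes,
P08,7,3,FATIGUE,,POWER_OUTAGE
P08,7,4,DYSPNEA,,POWER_OUTAGE
P08,7,4,WEIGHT,,POWER_OUTAGE
P08,7,4,MEDICATION,,POWER_OUTAGE
P08,7,4,FATIGUE,no,
P08,7,5,DYSPNEA,,POWER_OUTAGE
P08,7,5,WEIGHT,78.0,
P08,7,5,MEDICATION,yes,
P08,7,5,FATIGUE,,POWER_OUTAGE
P08,7,6,DYSPNEA,no,
P08,7,6,WEIGHT,,NOT_SEEN
P08,7,6,MEDICATION,,NOT_SEEN
P08,7,6,FATIGUE,no,
P08,7,7,DYSPNEA,,NOT_SEEN
P08,7,7,WEIGHT,,NOT_SEEN
P08,7,7,MEDICATION,,FORGOT
P08,7,7,FATIGUE,no,
P09,7,1,DYSPNEA,no,
P09,7,1,WEIGHT,69.5,
P09,7,1,MEDICATION,yes,
P09,7,1,FATIGUE,no,
P09,7,2,DYSPNEA,no,
P09,7,2,WEIGHT,69.5,
P09,7,2,MEDICATION,yes,
P09,7,2,FATIGUE,,FORGOT
P09,7,3,DYSPNEA,no,
P09,7,3,WEIGHT,69.5,
P09,7,3,MEDICATION,yes,
P09,7,3,FATIGUE,no,
P09,7,4,DYSPNEA,no,
P09,7,4,WEIGHT,69.5,
P09,7,4,MEDICATION,,FORGOT
P09,7,4,FATIGUE,no,
P09,7,5,DYSPNEA,no,
P09,7,5,WEIGHT,69.5,
P09,7,5,MEDICATION,yes,
P09,7,5,FATIGUE,no,
P09,7,6,DYSPNEA,no,
P09,7,6,WEIGHT,69.5,
P09,7,6,MEDICATION,yes,
P09,7,6,FATIGUE,no,
P09,7,7,DYSPNEA,no,
P09,7,7,WEIGHT,69.5,
P09,7,7,MEDICATION,yes,
P09,7,7,FATIGUE,no,
P10,3,1,DYSPNEA,no,
P10,3,1,WEIGHT,73.0,
P10,3,1,MEDICATION,yes,
P10,3,1,FATIGUE,no,
P10,3,2,DYSPNEA,no,
P10,3,2,WEIGHT,73.0,
P10,3,2,MEDICATION,yes,
P10,3,2,FATIGUE,no,
P10,3,3,DYSPNEA,no,
P10,3,3,WEIGHT,73.0,
P10,3,3,MEDICATION,yes,
P10,3,3,FATIGUE,no,
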