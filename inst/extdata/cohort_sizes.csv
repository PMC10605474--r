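patient_id,sb_allele1,sb_allele2,sb_homozygous,ogm_mean1,ogm_sd1,ogm_mean2,ogm_sd2,ogm_homozygous
Pt1,765,1242,FALSE,677,41,955,45,FALSE
Pt2,598,1035,FALSE,622,34,841,36,FALSE
Pt3,989,,TRUE,894,29,,,TRUE
Pt4,1127,1593,FALSE,866,48,1182,70,FALSE
Pt5,1447,1838,FALSE,1017,57,1180,40,FALSE
Pt6,917,,TRUE,664,24,730,22,FALSE
Pt7,1400,,TRUE,1223,36,,,TRUE
Pt8,991,,TRUE,829,53,,,TRUE
Pt9,1185,,TRUE,880,46,943,29,FALSE
Pt10,1256,4746,FALSE,1055,79,3226,163,FALSE
Pt11,249,810,FALSE,333,20,831,35,FALSE
Pt12,724,,TRUE,792,63,,,TRUE
Pt13,294,,TRUE,406,32,,,TRUE
Pt14,640,794,FALSE,652,40,759,24,FALSE
Pt15,605,714,FALSE,640,51,,,TRUE
Pt16,794,2386,FALSE,745,51,1646,97,FALSE
Pt17,810,,TRUE,582,35,654,24,FALSE
Control1,,,FALSE,-4,26,450,22,FALSE
Control2,,,FALSE,-6,30,,,TRUE
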