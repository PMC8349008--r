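block,level,n,pct
sex,female,295618,62.0
sex,male,180563,37.9
sex,missing,621,0.1
age,17_29,117782,24.7
age,30_40,118902,24.9
age,41_51,110361,23.1
age,52_63,129757,27.2
diagnosis,schizophrenia_psychotic,29887,6.3
diagnosis,bipolar,38984,8.2
diagnosis,depression_mood,205378,43.1
diagnosis,anxiety_stress,146790,30.8
diagnosis,other_mental,37031,7.8
diagnosis,substance_use,18732,3.9
insurance,medicaid_only,161843,33.9
insurance,medicare_only,21698,4.6
insurance,dual,42514,8.9
insurance,commercial_only,223103,46.8
insurance,commercial_plus_public,27644,5.8
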