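category_rank,category_name,icd10_prefix
1,schizophrenia_psychotic,F20-F29
2,bipolar,F30-F31
3,depression_mood,F32-F39
4,anxiety_stress,F40-F48
5,other_mental,F01-F09
5,other_mental,F50-F69
5,other_mental,F70-F99
6,substance_use,F10-F19
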