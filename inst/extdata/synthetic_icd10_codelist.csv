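condition,code,terminology
cardiovascular,I20,icd10-3char
cardiovascular,I21,icd10-3char
cardiovascular,I22,icd10-3char
cardiovascular,I25,icd10-3char
cardiovascular,I63,icd10-3char
cardiovascular,I64,icd10-3char
cardiovascular,G45,icd10-3char
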