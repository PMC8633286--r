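cohort,group,men,women
discovery,control,6,4
discovery,PD,7,3
discovery,MSA,3,2
validation,control,17,22
validation,PD,30,16
validation,MSA,12,5
validation,PSP,4,4
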