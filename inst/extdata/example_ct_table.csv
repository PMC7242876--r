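sample_id,group,gene,ct
s01,control,18s,10.12
s01,control,ucp1,25.30
s02,control,18s,10.05
s02,control,ucp1,25.11
s03,control,18s,9.98
s03,control,ucp1,25.20
s04,test,18s,10.08
s04,test,ucp1,21.95
s05,test,18s,10.15
s05,test,ucp1,22.10
s06,test,18s,10.02
s06,test,ucp1,21.80
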