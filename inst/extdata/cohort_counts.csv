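cohort,psa_density,gleason,nccn,patients
hamburg,<0.1,<=7,1,36
hamburg,0.03-0.31,6-7,2,13
hamburg,0.02-0.88,6-8,3,55
hamburg,0.04-0.98,6-9,4,13
hamburg,0.04-6,NA,NA,1
prococ,<0.1,<=7,1,47
prococ,0.01-0.31,6-7,2,30
prococ,0.02-0.53,6-9,3,146
prococ,0.03-0.93,7-9,4,40
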