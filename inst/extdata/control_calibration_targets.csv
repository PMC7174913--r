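outcome,arm,target,tolerance
mi,control,0.1056,0.002
stroke,control,0.2417,0.002
chf,control,0.1489,0.002
esrd,control,0.0461,0.002
blindness,control,0.0579,0.002
neuropathy,control,0.2128,0.002
minor_amputation,control,0.1221,0.002
major_amputation,control,0.0922,0.002
ly,control,27.87,0.05
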