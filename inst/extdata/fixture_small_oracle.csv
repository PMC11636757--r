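kind,name,value
entropy,pH,0.770932752278422
entropy,TH,0.780852139704473
entropy,Ca,0.795218141654204
entropy,NO3,0.777249587944716
weight,pH,0.261567723029134
weight,TH,0.250240954978777
weight,Ca,0.233836678695724
weight,NO3,0.254354643296365
score,F-01,45.2958097709229
score,F-02,29.6353671227906
score,F-03,84.3056010127986
score,F-04,45.0974923141806
score,F-05,55.6072405503113
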