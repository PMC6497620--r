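food,medium_g
grape,125
grapes,125
grape juice,204
wine,125
raisins,30
apple,112
wholegrain,76
poultry_fish,120
red_meat,90
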