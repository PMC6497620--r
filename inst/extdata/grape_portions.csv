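day,meal,food,grams,medium_g,portion_class
1,breakfast,none,0,125,none
1,lunch,none,0,125,none
1,dinner,red wine,200,125,large
2,breakfast,red berry smoothie (10% grape),31,125,small
2,lunch,none,0,125,none
2,dinner,raisins,43,30,medium
3,breakfast,none,0,125,none
3,lunch,none,0,125,none
3,dinner,white wine,201,125,large
4,breakfast,none,0,125,none
4,lunch,none,0,125,none
4,dinner,none,0,125,none
5,breakfast,red grape juice,204,204,medium
5,lunch,red grapes,125,125,medium
5,afternoon_snack,red grapes & red grape juice,208,125,large
6,breakfast,white grape juice,204,204,medium
6,lunch,white grapes,125,125,medium
6,afternoon_snack,white grapes & white grape juice,228,125,large
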