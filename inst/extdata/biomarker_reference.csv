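name,formula,food_group,adducts,msi_evidence
"HHPAA glucuronide",C14H17NO9,rye_bread,[M-H]-,library
"Isopropyl 2-hydroxyphenylcarbamate",C10H13NO3,rye_bread,[M-H]-,library
"Ferulic acid 4-O-sulfate",C10H10O7S,wholegrain_coffee,[M-H]-;[M-SULP-H]-,standard
"Ferulic acid 4-O-glucuronide",C16H18O10,wholegrain_coffee,[M-H]-,standard
"Caffeine",C8H10N4O2,coffee,[M+H]+,standard
"Trigonelline",C7H7NO2,coffee,[M+Na]+;[M+Na]+ 13C,standard
"Sucrose",C12H22O11,sweetened_cereal,[M-H]-;[M+Na]+;[M+K]+,standard
"Anserine",C10H16N4O3,oily_fish,[M-H]-;[M+H]+;[M+H]+ 13C;[M+Na]+;[M+K]+,standard
"Trimethylamine N-oxide",C3H9NO,oily_fish,[2M+H]+,standard
"S-Methyl-L-cysteine sulfoxide",C4H9NO3S,broccoli,[M+Na]+,standard
"Tartaric acid",C4H6O6,grape,[M-H]-;[M-H]- 13C;[M+Na-2H]-,standard
"4-Hydroxy-5-(3,4-dihydroxyphenyl)-valeric acid",C11H14O5,almond,[M-H]-;[M+Na]+,library
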