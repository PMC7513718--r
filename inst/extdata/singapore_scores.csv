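sample_id,locality,score_pct
BL01,Captive,5.00
BL02,Captive,10.00
RJF01_GR,Sin Ming,37.50
RJF02_GR,Sin Ming,18.75
RJF04_OR,Oxley Rise,40.63
RJF06_MBC,Maple Business City,40.00
RJF07_SR,Sime Road,70.00
RJF10_SM,Sin Ming,75.00
RJF11_SM,Sin Ming,30.00
RJF14_SM,Sin Ming,43.75
RJF15_SM,Sin Ming,20.00
RJF19_SM,Sin Ming,65.63
RJF20_SM,Sin Ming,62.50
RJF21_SM,Sin Ming,10.00
RJF22_SM,Sin Ming,10.00
RJF24_SM,Sin Ming,65.00
RJF25_SM,Sin Ming,50.00
RJF26_LP,Sin Ming,81.25
RJF27_LP,Sin Ming,75.00
RJF28_LP,Sin Ming,70.00
RJF29_LP,Sin Ming,55.00
RJF30_LP,Sin Ming,45.00
RJF32_SC,Sin Ming,40.00
RJF33_LAS,Lor Ah Soo,71.88
RJF34_GIS,Global Indian School,53.13
RJF35_GIS,Global Indian School,46.88
RJF31_CR,Coronation Road,46.875
RJF38_RR,Rifle Range,10.00
RJF39_GIS,Global Indian School,35.00
RJF40_WR,Woking Road,50.00
RJF42_LAS,Lor Ah Soo,40.00
RJF43_LAS,Lor Ah Soo,59.38
RJF44_WR,Woking Road,43.75
RJF45_WR,Woking Road,46.88
RJF46_BV,Braddell View,46.88
RJF47_BV,Braddell View,46.88
RJF48_BV,Braddell View,20.00
RJF49_DE,Singapore Botanic Garden,59.38
RJF50_LD,Linden Drive,81.25
RJF51_BV,Braddell View,40.63
RJF54_RV,Pasir Ris,65.63
RJF55_RV,Pasir Ris,62.50
RJF58_BV,Braddell View,59.38
RJF59_BV,Braddell View,90.00
RJF61_BV,Braddell View,62.50
RJF62_RV,Pasir Ris,46.88
RJF63_BV,Braddell View,59.38
RJF66_PP,Pasir Ris,80.00
S01,Captive,10.00
S02,Captive,10.00
WL01,Captive,18.75
WL02,Captive,18.75
WL03,Captive,15.63
WL04,Captive,10.00
H0031_PP,Pasir Ris,81.25
H0032_PP,Pasir Ris,80.00
H0033_SBG,Singapore Botanic Garden,60.00
H0034_SBG,Singapore Botanic Garden,75.00
H0035_BV,Braddell View,71.88
H0036_SM,Sin Ming,78.13
H0037_LDel,Lower Delta,68.75
H0038_CR,Coronation Road,50.00
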