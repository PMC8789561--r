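indicator,region,year,value
u5mr,World,1990,93.0
u5mr,World,2000,75.8
u5mr,World,2010,51.2
u5mr,World,2019,37.7
nmr,World,1990,36.6
nmr,World,2000,30.3
nmr,World,2010,22.2
nmr,World,2019,17.5
u5_deaths_thousands,World,1990,12494
u5_deaths_thousands,World,2019,5189
neonatal_deaths_thousands,World,1990,5014
neonatal_deaths_thousands,World,2019,2440
u5mr,Sub-Saharan Africa,2019,75.8
u5mr,West and central Africa,2019,94.7
u5mr,High income,2019,5.0
nmr,High income,2019,2.9
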