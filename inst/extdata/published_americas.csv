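america_id,label,races,n_counties,population_2021_millions,pct_national_printed
1,Asian,asian_nhpi,2803,20.67,6.21
2,Latino | Other counties,latino,2777,46.17,13.88
3,White (majority) Asian AIAN | Other counties,aian;asian_nhpi;white,2381;340;2662,193.20,58.08
4,White | Non-metropolitan and low-income Northlands,white,47,0.29,0.09
5,Latino | Southwest,latino,366,16.47,4.95
6,Black | Other counties,black,2700,31.78,9.55
7,Black | Highly segregated metropolitan areas,black,88,10.26,3.08
8,White | Low-income Appalachia and Lower Mississippi Valley,white,434,10.34,3.11
9,Black | Non-metropolitan and low-income South,black,355,2.13,0.64
10,AIAN | West,aian,762,1.32,0.40
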