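america_id,label,year,mean,lower,upper
1,Asian,2000,83.1,82.7,83.5
1,Asian,2010,85.2,84.8,85.5
1,Asian,2019,86.0,85.6,86.3
1,Asian,2020,83.7,83.4,84.1
1,Asian,2021,84.0,83.6,84.4
2,Latino | Other counties,2000,80.4,80.1,80.7
2,Latino | Other counties,2010,82.7,82.4,83.0
2,Latino | Other counties,2019,83.0,82.8,83.3
2,Latino | Other counties,2020,79.2,78.9,79.4
2,Latino | Other counties,2021,79.4,79.2,79.7
3,White (majority) Asian AIAN | Other counties,2000,77.5,77.4,77.5
3,White (majority) Asian AIAN | Other counties,2010,79.1,79.0,79.1
3,White (majority) Asian AIAN | Other counties,2019,79.3,79.2,79.3
3,White (majority) Asian AIAN | Other counties,2020,77.9,77.8,77.9
3,White (majority) Asian AIAN | Other counties,2021,77.2,77.2,77.3
4,White | Non-metropolitan and low-income Northlands,2000,77.6,77.0,78.1
4,White | Non-metropolitan and low-income Northlands,2010,78.8,78.3,79.4
4,White | Non-metropolitan and low-income Northlands,2019,78.6,78.1,79.2
4,White | Non-metropolitan and low-income Northlands,2020,77.0,76.5,77.6
4,White | Non-metropolitan and low-income Northlands,2021,76.7,76.2,77.3
5,Latino | Southwest,2000,77.8,77.6,78.0
5,Latino | Southwest,2010,80.1,79.9,80.4
5,Latino | Southwest,2019,80.4,80.2,80.6
5,Latino | Southwest,2020,76.5,76.3,76.7
5,Latino | Southwest,2021,76.0,75.7,76.2
6,Black | Other counties,2000,72.0,71.9,72.1
6,Black | Other counties,2010,75.4,75.3,75.5
6,Black | Other counties,2019,75.7,75.6,75.8
6,Black | Other counties,2020,72.8,72.6,72.9
6,Black | Other counties,2021,72.3,72.1,72.4
7,Black | Highly segregated metropolitan areas,2000,70.6,70.5,70.8
7,Black | Highly segregated metropolitan areas,2010,74.3,74.2,74.5
7,Black | Highly segregated metropolitan areas,2019,74.9,74.7,75.0
7,Black | Highly segregated metropolitan areas,2020,70.8,70.7,70.9
7,Black | Highly segregated metropolitan areas,2021,71.5,71.3,71.6
8,White | Low-income Appalachia and Lower Mississippi Valley,2000,74.8,74.7,74.9
8,White | Low-income Appalachia and Lower Mississippi Valley,2010,75.3,75.2,75.4
8,White | Low-income Appalachia and Lower Mississippi Valley,2019,74.8,74.7,74.9
8,White | Low-income Appalachia and Lower Mississippi Valley,2020,72.8,72.7,72.9
8,White | Low-income Appalachia and Lower Mississippi Valley,2021,71.1,71.0,71.2
9,Black | Non-metropolitan and low-income South,2000,70.5,70.3,70.7
9,Black | Non-metropolitan and low-income South,2010,72.8,72.6,73.0
9,Black | Non-metropolitan and low-income South,2019,72.5,72.2,72.7
9,Black | Non-metropolitan and low-income South,2020,68.5,68.3,68.7
9,Black | Non-metropolitan and low-income South,2021,68.0,67.8,68.3
10,AIAN | West,2000,72.3,71.0,73.6
10,AIAN | West,2010,71.2,70.0,72.4
10,AIAN | West,2019,70.2,68.9,71.4
10,AIAN | West,2020,64.8,63.7,66.0
10,AIAN | West,2021,63.6,62.3,65.0
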