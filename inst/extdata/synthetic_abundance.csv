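"sample_id","TG(33:9)","TG(45:6)","TG(44:5)","PC(31:3)","TG(39:9)","TG(51:1)","TG(37:2)"
"F_serum_1",33.75,42.85,43.48,0,98.22,130.03,43.34
"F_serum_2",47.17,37.69,34.83,0,42.93,45.78,71.55
"F_serum_3",62.14,97.54,78.53,0,44.28,77.04,86.99
"F_serum_4",30.69,90.56,36.43,0,88.02,100.71,49.17
"F_liver_1",60.21,52.67,0,32.53,28.66,0,74.34
"F_liver_2",55.43,30.93,0,107.89,59.93,0,44.59
"F_liver_3",56.98,85.65,0,86.38,53.75,0,92.44
"F_liver_4",95.42,83.59,0,36.87,68.96,0,73.78
"F_vastus_muscle_1",29.68,78.56,0,0,0,81.22,0
"F_vastus_muscle_2",102.89,78.91,0,0,0,54.42,0
"F_vastus_muscle_3",37.62,45.78,0,0,0,60.92,0
"F_vastus_muscle_4",31.01,77.69,0,0,0,35.05,0
"M_serum_1",38.16,104.6,62.4,0,91.11,68.03,90.81
"M_serum_2",61.95,55.65,22.91,0,62.41,35.05,74
"M_serum_3",58.91,33.46,26.96,0,61.31,35.63,60.54
"M_serum_4",46.81,81.2,43.52,0,79.34,33.28,21.14
"M_liver_1",33.9,80.9,0,72.73,100.34,0,38.81
"M_liver_2",39.48,46.75,0,86.41,66.13,0,69.45
"M_liver_3",100.7,127.67,0,62.06,33.31,0,43.31
"M_liver_4",60.33,36.7,0,65.1,50.48,0,47.47
"M_vastus_muscle_1",40.88,64.99,0,0,0,39.43,0
"M_vastus_muscle_2",34.08,17.59,0,0,0,92.48,0
"M_vastus_muscle_3",49.31,50.34,0,0,0,44.91,0
"M_vastus_muscle_4",23.73,96.1,0,0,0,52.7,0
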