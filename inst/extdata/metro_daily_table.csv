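weekday,week,volume
Sunday,2,1.00
Sunday,3,1.26
Sunday,4,1.62
Sunday,5,0.93
Sunday,6,0.55
Sunday,7,1.28
Sunday,8,1.43
Monday,2,0.86
Monday,3,0.96
Monday,4,1.57
Monday,5,0.65
Monday,6,0.60
Monday,7,1.12
Monday,8,1.34
Tuesday,2,1.75
Tuesday,3,2.05
Tuesday,4,2.38
Tuesday,5,0.97
Tuesday,6,1.03
Tuesday,7,1.07
Wednesday,2,1.79
Wednesday,3,2.10
Wednesday,4,2.23
Wednesday,5,0.78
Wednesday,6,1.11
Wednesday,7,1.70
Thursday,2,1.90
Thursday,3,2.12
Thursday,4,2.09
Thursday,5,0.68
Thursday,6,1.22
Thursday,7,1.74
Friday,2,1.97
Friday,3,2.14
Friday,4,1.90
Friday,5,0.62
Friday,6,1.22
Friday,7,1.77
Saturday,1,1.81
Saturday,2,2.16
Saturday,3,2.33
Saturday,4,1.72
Saturday,5,0.67
Saturday,6,1.40
Saturday,7,1.90
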