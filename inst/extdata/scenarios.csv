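id,gcsf_derivative,gcsf_dose_ug,gcsf_per_kg,gcsf_days,disease,chemotherapy,regimen,risk_group,validation,note
1,fil,5,1,2-13,Breast cancer,TA,ta,all,0,
2,fil,5,1,2-6,NSCLC,CP,cp,all,0,
3,fil,480,0,6-13,NHL,high-CHOEP-14,hchoep14,all,0,
4,peg,30,1,2,Breast cancer,TA,ta,all,0,
5,peg,60,1,2,Breast cancer,TA,ta,all,0,
6,peg,100,1,2,Breast cancer,TA,ta,all,0,
7,peg,6000,0,2,Breast cancer,TA,ta,all,0,
8,peg,6000,0,2,Breast cancer,TA,ta,all,0,
9,peg,30,1,2,NSCLC,CP,cp,all,0,
10,peg,100,1,2,NSCLC,CP,cp,all,0,
11,peg,300,1,2,NSCLC,CP,cp,all,0,
12,peg,6000,0,2,NHL,CHOP-14,chop14,elderly,1,held out for model validation
13,peg,6000,0,2,DLBCL,R CHOP-14,chop14,elderly,0,rituximab treated as plain CHOP
14,none,,,,NHL,CHOP-21 (young),chop21,young,0,
15,none,,,,NHL,CHOP-21 (elderly),chop21,elderly,0,
16,none,,,,NHL,CHOEP-21 (young),choep21,young,0,
17,none,,,,NHL,CHOEP-21 (elderly),choep21,elderly,0,
18,none,,,,HD,BEACOPP-21,beacopp21,all,0,
19,none,,,,Breast cancer,EC-T,ect,all,0,
20,fil,480,0,4-13,NHL,CHOP-14 (young),chop14,young,0,
21,fil,480,0,4-13,NHL,CHOP-14 (elderly),chop14,elderly,0,
22,fil,480,0,6-12,NHL,CHOP-14,chop14,elderly,1,held out for model validation
23,fil,480,0,4-13,NHL,CHOEP-14 (young),choep14,young,0,
24,fil,480,0,4-13,NHL,CHOEP-14 (elderly),choep14,elderly,0,
25,fil,480,0,6-13,NHL,high-CHOEP-21,hchoep21,all,0,
26,fil,480,0,8-13,HD,BEACOPP-14,beacopp14,all,0,
27,fil,480,0,8-15,HD,BEACOPP-21 escalated,beacopp_esc,all,0,
28,fil,480,0,3-10,Breast cancer,E-T-C,etc,all,0,
29,fil,5,1,5-16,relapsed or persistent HD or NHL,ESHAP,eshap,all,0,
30,peg,6000,0,2,NHL,CHOP-14,chop14,elderly,0,
31,peg,6000,0,4,NHL,CHOP-14,chop14,elderly,0,
32,peg,100,1,6,relapsed or persistent HD or NHL,ESHAP,eshap,all,1,held out for validation; day 6 per the data-set table (a figure caption says day 5)
33,peg,6000,0,2,DLBCL,R CHOP-14,chop14,young,0,rituximab treated as plain CHOP
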