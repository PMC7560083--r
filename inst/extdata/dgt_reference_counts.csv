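variable,state,year,n
driving_license,Valid,2016,85321
driving_license,Valid,2017,84284
driving_license,Valid,2018,83701
driving_license,Invalid,2016,2532
driving_license,Invalid,2017,2139
driving_license,Invalid,2018,2386
driving_license,Other,2016,67857
driving_license,Other,2017,69562
driving_license,Other,2018,69649
right_of_way_violation,No,2016,50530
right_of_way_violation,No,2017,48676
right_of_way_violation,No,2018,48417
right_of_way_violation,Yes,2016,32597
right_of_way_violation,Yes,2017,33666
right_of_way_violation,Yes,2018,34117
right_of_way_violation,Unknown,2016,72583
right_of_way_violation,Unknown,2017,73643
right_of_way_violation,Unknown,2018,73202
speed_infringement,No,2016,65579
speed_infringement,No,2017,64692
speed_infringement,No,2018,62393
speed_infringement,Yes,2016,8423
speed_infringement,Yes,2017,7674
speed_infringement,Yes,2018,7880
speed_infringement,Unknown,2016,81708
speed_infringement,Unknown,2017,83619
speed_infringement,Unknown,2018,85463
other_infringements,No,2016,59762
other_infringements,No,2017,60196
other_infringements,No,2018,60133
other_infringements,Yes,2016,578
other_infringements,Yes,2017,572
other_infringements,Yes,2018,562
other_infringements,Unknown,2016,95370
other_infringements,Unknown,2017,95217
other_infringements,Unknown,2018,95041
distraction,No,2016,38804
distraction,No,2017,38884
distraction,No,2018,38857
distraction,Technology,2016,326
distraction,Technology,2017,371
distraction,Technology,2018,354
distraction,Other,2016,8767
distraction,Other,2017,9673
distraction,Other,2018,10042
distraction,Unknown,2016,107813
distraction,Unknown,2017,107057
distraction,Unknown,2018,106483
accident_severity,NoneMild,2016,142783
accident_severity,NoneMild,2017,142946
accident_severity,NoneMild,2018,143530
accident_severity,SeriousDeath,2016,12890
accident_severity,SeriousDeath,2017,12967
accident_severity,SeriousDeath,2018,12163
accident_type,Collision,2016,119137
accident_type,Collision,2017,116680
accident_type,Collision,2018,115177
accident_type,RunOver,2016,13169
accident_type,RunOver,2017,12576
accident_type,RunOver,2018,12302
accident_type,Other,2016,23367
accident_type,Other,2017,26657
accident_type,Other,2018,28214
age_band,<25,2016,21541
age_band,<25,2017,20962
age_band,<25,2018,20248
age_band,25-40,2016,60012
age_band,25-40,2017,58462
age_band,25-40,2018,57984
age_band,41-60,2016,54369
age_band,41-60,2017,55976
age_band,41-60,2018,57696
age_band,>60,2016,16604
age_band,>60,2017,17393
age_band,>60,2018,17627
age_band,Unknown,2016,3184
age_band,Unknown,2017,3192
age_band,Unknown,2018,2181
gender,Men,2016,110443
gender,Men,2017,111068
gender,Men,2018,111061
gender,Women,2016,43971
gender,Women,2017,43711
gender,Women,2018,44128
gender,Unknown,2016,1296
gender,Unknown,2017,1206
gender,Unknown,2018,547
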