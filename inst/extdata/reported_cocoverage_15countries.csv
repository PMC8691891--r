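country,p0,p1,p2,p3,p4,p5,mean_reported,sd_reported
Benin,39.2,6.7,10.5,8.1,9.3,26.3,2.2,2.10
Burundi,89.3,3.8,2,1.4,1.2,2.2,0.3,0.96
Cameroon,37.9,5.8,8.4,9.5,10.2,28.3,2.3,2.12
Ethiopia,63.6,10.8,10.5,6.1,4.3,4.7,0.9,1.46
Guinea,50.6,5.2,5.5,6.2,8.8,23.7,1.9,2.15
Malawi,12.5,5,8.6,12.3,17.6,43.9,3.5,1.76
Mali,53,9.6,7.9,6.1,7.1,16.3,1.5,1.95
Nepal,40.1,5.1,8.2,8.5,11.9,26.2,2.3,2.12
Nigeria,72.6,3.8,4,3.1,3.6,12.9,1,1.81
Pakistan,29.9,13.4,15.4,13.8,14,13.6,2.1,1.80
Senegal,27.1,4,16.8,14.4,14.5,23.2,2.5,1.91
Tanzania,50.3,9.9,9.1,8.6,9.2,12.8,1.5,1.88
Uganda,49.6,8.6,8.2,7.7,7.7,18.2,1.7,2.00
Zambia,32.6,3.5,5.2,5.6,8.9,44.2,2.9,2.23
Zimbabwe,14.7,2.9,5.7,9.6,17.3,49.8,3.6,1.81
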