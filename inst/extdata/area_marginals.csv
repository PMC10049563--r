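area,element,min,max,mean,sd,cv,skewness,kurtosis
A,Zn,43.44,132.06,56.97,16.87,29.61,3.59,15.28
A,Cu,17.44,29.44,23.27,3.21,13.79,0.08,-1.06
A,Cr,23.81,43.00,33.33,5.30,15.91,0.18,-0.86
A,Pb,69.38,129.38,107.87,18.05,16.73,-0.99,-0.45
A,As,75.38,126.13,106.91,11.88,11.11,-1.28,2.14
A,Hg,0.02,0.05,0.03,0.01,23.92,1.41,2.14
B,Zn,34.31,73.88,58.00,8.41,14.50,-0.63,0.63
B,Cu,16.81,119.19,30.82,16.35,53.05,4.67,25.05
B,Cr,23.69,64.94,39.56,9.57,24.19,0.84,0.82
B,Pb,45.63,102.50,70.98,10.76,15.16,0.15,1.48
B,As,66.88,109.69,89.93,11.74,13.05,-0.06,-0.70
B,Hg,0.02,0.05,0.03,0.01,19.38,0.21,-0.78
C,Zn,20.63,70.38,55.80,7.84,14.04,-1.83,8.51
C,Cu,6.38,47.56,28.34,8.67,30.59,-0.45,0.34
C,Cr,9.06,66.19,37.80,14.12,37.35,-0.23,-0.50
C,Pb,36.25,110.63,81.19,11.98,14.76,-0.97,3.73
C,As,6.19,141.63,73.09,27.11,37.10,0.45,0.65
C,Hg,0.01,0.06,0.03,0.01,37.95,-0.17,-0.01
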