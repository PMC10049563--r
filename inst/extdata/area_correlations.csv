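area,row,col,r
A,Cu,Zn,0.06
A,Cr,Zn,0.10
A,Pb,Zn,-0.15
A,As,Zn,-0.002
A,Hg,Zn,-0.06
A,Cr,Cu,0.21
A,Pb,Cu,-0.49
A,As,Cu,-0.49
A,Hg,Cu,0.45
A,Pb,Cr,-0.01
A,As,Cr,-0.53
A,Hg,Cr,0.01
A,As,Pb,0.35
A,Hg,Pb,-0.46
A,Hg,As,-0.44
B,Cu,Zn,0.38
B,Cr,Zn,0.45
B,Pb,Zn,0.09
B,As,Zn,-0.58
B,Hg,Zn,0.41
B,Cr,Cu,0.40
B,Pb,Cu,0.11
B,As,Cu,-0.37
B,Hg,Cu,0.35
B,Pb,Cr,0.02
B,As,Cr,-0.58
B,Hg,Cr,0.54
B,As,Pb,-0.01
B,Hg,Pb,0.01
B,Hg,As,-0.62
C,Cu,Zn,0.66
C,Cr,Zn,0.59
C,Pb,Zn,0.61
C,As,Zn,-0.62
C,Hg,Zn,0.36
C,Cr,Cu,0.80
C,Pb,Cu,0.32
C,As,Cu,-0.84
C,Hg,Cu,0.76
C,Pb,Cr,0.39
C,As,Cr,-0.85
C,Hg,Cr,0.79
C,As,Pb,-0.29
C,Hg,Pb,0.09
C,Hg,As,-0.80
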