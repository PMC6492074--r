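v -8.8013152417780915e+01
nai  6.4693559352022829e+00
nass  6.4694156878019422e+00
ki  1.4549431328029178e+02
kss  1.4549429617405480e+02
cai  7.4531326180010161e-05
cass  7.3044737811143453e-05
cansr  1.3789540410511738e+00
cajsr  1.3794260460952634e+00
m  7.3358082454001777e-03
hf  6.9849721611191584e-01
hs  6.9849712849340584e-01
j  6.9849653178495785e-01
hsp  4.5547302391351513e-01
jp  6.9849605624220101e-01
mL  1.8785945782108377e-04
hL  5.1335230537903775e-01
hLp  3.0788590440895636e-01
a  1.0003331506997103e-03
iF  9.9955511091954274e-01
iS  8.7170956728106286e-01
ap  5.0969655011903628e-04
iFp  9.9955511096046845e-01
iSp  9.0545923720970767e-01
d  2.3345362006176398e-09
ff  9.9999999090431413e-01
fs  9.7189683426065365e-01
fcaf  9.9999999090431446e-01
fcas  9.9999997830861187e-01
jca  9.9999999084792712e-01
nca  1.5390431385805508e-03
ffp  9.9999999090429736e-01
fcafp  9.9999999090429847e-01
xs1  1.3094183821077479e-01
xs2  1.9254512244458360e-04
xk1  9.9675640834526247e-01
Jrelnp  1.4654134299480265e-07
Jrelp  1.8317578289992775e-07
CaMKt  3.2522690592576174e-03
IC1  9.9963691119835918e-01
IC2  6.8335832856390843e-05
C1  1.8018317017076579e-08
C2  8.2680034022942234e-05
O  1.5555024256842044e-04
IO  5.6778842054991060e-05
IObound  0.0000000000000000e+00
Obound  0.0000000000000000e+00
Cbound  0.0000000000000000e+00
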