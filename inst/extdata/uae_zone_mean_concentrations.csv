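zone,Cd,Cr,Cu,Ni,Pb,Co,Ba,Fe,Mn,Zn
KF,33.219,104.14,59.970,1325.4,103.9,33.192,57.679,17051,233.667,712.86
D,25.885,89.152,62.682,201.34,33.748,28.767,94.57,10915,197.313,313.39
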