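human,chimpanzee,mouse,rat
MMP1,MMP1,Mmp1a,Mmp1
MMP2,MMP2,Mmp2,Mmp2
MMP3,MMP3,Mmp3,Mmp3
MMP7,MMP7,Mmp7,Mmp7
MMP9,MMP9,Mmp9,Mmp9
MMP12,MMP12,Mmp12,Mmp12
MMP13,MMP13,Mmp13,Mmp13
MMP14,MMP14,Mmp14,Mmp14
CTSB,CTSB,Ctsb,Ctsb
CTSD,CTSD,Ctsd,Ctsd
CTSE,CTSE,Ctse,Ctse
CTSG,CTSG,Ctsg,Ctsg
CTSK,CTSK,Ctsk,Ctsk
CTSL,CTSL,Ctsl,Ctsl
CTSS,CTSS,Ctss,Ctss
ELANE,ELANE,Elane,Elane
PRTN3,PRTN3,Prtn3,Prtn3
GZMA,GZMA,Gzma,Gzma
GZMB,GZMB,Gzmb,Gzmb
GZMH,GZMH,,
KLK3,KLK3,,
F2,F2,F2,F2
F10,F10,F10,F10
PLAU,PLAU,Plau,Plau
PLAT,PLAT,Plat,Plat
ADAM17,ADAM17,Adam17,Adam17
CASP3,CASP3,Casp3,Casp3
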