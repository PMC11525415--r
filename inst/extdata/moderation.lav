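# simple latent moderation model
Xi1 =~ 1*x1 + 1*x2 + 1*x3
Xi2 =~ 1*x4 + 1*x5 + 1*x6
Eta1 =~ 1*y1 + 1*y2 + 1*y3
Eta1 ~ 0.2*Xi1 + 0.5*Xi2 + 0.1*Xi1:Xi2
Xi1 ~~ 1*Xi1
Xi2 ~~ 1*Xi2
Xi1 ~~ 0.5*Xi2
Eta1 ~~ 0.5975*Eta1
x1 ~~ 0.25*x1
x2 ~~ 0.25*x2
x3 ~~ 0.25*x3
x4 ~~ 0.25*x4
x5 ~~ 0.25*x5
x6 ~~ 0.25*x6
y1 ~~ 0.25*y1
y2 ~~ 0.25*y2
y3 ~~ 0.25*y3
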