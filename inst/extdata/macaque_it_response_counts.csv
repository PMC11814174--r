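monkey,area,session,only_dog,only_cat,both,none
X,TEO,pre,3,1,84,5
X,TEO,post,1,1,94,1
X,TE,pre,8,7,61,74
X,TE,post,8,5,45,77
R,TE,pre,7,6,89,46
R,TE,post,9,4,92,32
L,TEO,pre,1,3,57,17
L,TEO,post,3,2,51,17
L,TE,pre,2,6,30,19
L,TE,post,3,8,23,35
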