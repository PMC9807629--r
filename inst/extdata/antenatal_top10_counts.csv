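rank,option,p_t,n_t,N_p,N
1,Feel pressure now,138,646,407,5666
2,Children will influence the relationship with lover,83,322,407,5666
3,Staff,102,578,407,5666
4,Occasionally passive smoking,124,937,407,5666
5,Own wishes (the reason for wanting a baby),82,494,407,5666
6,Worried about economic pressure,92,707,407,5666
7,Cesarean section,73,431,407,5666
8,Drinking occasionally,72,443,407,5666
9,Passive smoking > 3 hours/day,41,79,407,5666
10,General (relationship with colleagues),44,115,407,5666
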