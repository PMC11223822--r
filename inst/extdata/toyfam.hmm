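HMMER3/f [3.4 | Aug 2023]
NAME  toyfam
LENG  12
ALPH  amino
RF    no
MM    no
CONS  yes
CS    no
MAP   yes
DATE  Fri Sep 18 06:05:48 2026
NSEQ  6
EFFN  6.000000
CKSUM 777625069
STATS LOCAL MSV       -5.9504  0.76666
STATS LOCAL VITERBI   -6.1954  0.76666
STATS LOCAL FORWARD   -2.6134  0.76666
HMM          A        C        D        E        F        G        H        I        K        L        M        N        P        Q        R        S        T        V        W        Y   
            m->m     m->i     m->d     i->m     i->i     d->m     d->d
  COMPO   2.30331  3.21774  2.91710  2.53657  3.69148  2.57225  3.85550  3.27020  2.59717  2.70005  4.29486  2.51274  2.52551  3.92930  4.20797  2.46019  3.51412  3.24653  3.43310  3.53948
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00606  5.50481  6.22715  0.61958  0.77255  0.00000        *
      1   3.34108  5.62989  3.53656  1.88637  5.28158  4.01074  4.52433  4.75680  3.34467  4.28595  5.05782  3.68821  1.87777  3.65871  3.82815  1.21857  1.97067  4.27791  6.44623  5.06592      1 s - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00606  5.50481  6.22715  0.61958  0.77255  0.48576  0.95510
      2   0.74700  5.34080  4.49014  4.20528  4.70995  4.18751  5.13458  4.57352  4.20586  4.23037  5.12294  1.91315  4.88005  4.53682  4.49270  3.64086  3.90169  4.16059  1.76126  4.76769      2 a - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00606  5.50481  6.22715  0.61958  0.77255  0.48576  0.95510
      3   1.85156  5.25475  4.44796  4.18564  4.93849  4.20952  5.23549  1.88289  4.27613  3.93026  4.89880  0.73329  4.88649  4.56453  4.57662  3.65986  3.85884  3.58366  6.42743  5.18702      3 n - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00606  5.50481  6.22715  0.61958  0.77255  0.48576  0.95510
      4   3.79602  6.04419  0.68885  3.27867  5.46525  4.20299  4.87927  4.96636  3.94124  1.95656  5.46077  3.82297  4.85464  4.08322  4.49617  1.91747  4.14443  4.58243  6.79604  5.35429      4 D - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00606  5.50481  6.22715  0.61958  0.77255  0.48576  0.95510
      5   3.19946  4.80288  4.31577  3.75835  3.93459  2.22219  4.53050  2.21904  3.67544  1.30335  3.92279  4.08326  4.61213  2.51762  3.95669  2.07268  3.44076  3.07047  5.41784  4.20728      5 l - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00606  5.50481  6.22715  0.61958  0.77255  0.48576  0.95510
      6   3.49558  0.82732  5.32755  4.90471  4.29598  4.39203  1.77682  3.59713  4.60052  3.55198  4.55587  4.81471  5.01737  4.91194  4.70258  3.82830  3.88572  1.82439  5.87043  4.52764      6 c - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00606  5.50481  6.22715  0.61958  0.77255  0.48576  0.95510
      7   1.49475  5.37012  5.43396  5.46971  6.22947  0.39657  6.25729  5.76827  5.62481  5.45749  6.21336  4.99645  5.01722  5.69809  5.63951  3.67797  4.05814  4.81675  7.49340  6.53209      7 G - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00606  5.50481  6.22715  0.61958  0.77255  0.48576  0.95510
      8   3.50222  5.42025  5.09650  5.10800  6.13655  4.16335  6.09160  5.75834  5.33261  5.40845  6.18528  4.89044  0.50666  5.48829  5.44759  1.29733  4.08673  4.84128  7.40801  6.34753      8 P - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00606  5.50481  6.22715  0.61958  0.77255  0.48576  0.95510
      9   4.46615  5.69686  5.94312  5.57691  1.54275  5.40529  4.67963  4.05791  5.37096  1.37049  4.63868  5.24271  2.00102  5.27761  5.30258  4.75819  4.68517  4.00076  4.81897  1.30626      9 y - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00606  5.50481  6.22715  0.61958  0.77255  0.48576  0.95510
     10   3.36384  5.33044  3.70911  1.09416  4.57453  4.19258  4.48594  2.26672  3.36101  3.53246  4.45051  2.09653  4.61807  3.68732  3.79871  3.47905  3.60741  2.00105  5.97184  4.66689     10 e - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00606  5.50481  6.22715  0.61958  0.77255  0.48576  0.95510
     11   2.00408  5.69414  3.36533  1.06824  5.02975  4.00660  4.30313  4.48158  3.10090  4.02184  2.50864  2.06927  4.46333  3.43119  3.58992  3.29775  3.56760  4.09019  6.20517  4.81513     11 e - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00606  5.50481  6.22715  0.61958  0.77255  0.48576  0.95510
     12   4.94870  6.62762  5.58642  4.78645  5.26114  5.24330  5.14548  5.67855  0.38158  4.95989  5.98702  5.02190  5.64522  4.42225  3.53577  4.96503  5.08037  5.42662  1.64830  5.07852     12 K - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00408  5.50283        *  0.61958  0.77255  0.00000        *
//
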