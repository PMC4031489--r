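chr17	65849385	65851386	sv_01
chr12	49219217	49221218	sv_02
chr10	75540867	75542868	sv_03
chr3	71246488	71248489	sv_04
chr7	142963823	142965824	sv_05
chr5	52239782	52241783	sv_06
chr12	55027593	55029594	sv_07
chr16	30766745	30768746	sv_08
chr5	139935827	139937828	sv_09
chrX	10175454	10177455	sv_10
chr16	28999900	29001901	sv_11
chr4	44176009	44178010	sv_12
chr4	8054945	8056946	sv_13
chr11	35455265	35457266	sv_14
chr2	179399886	179401887	sv_15
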