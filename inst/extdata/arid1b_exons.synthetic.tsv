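# Synthetic transcript model of ARID1B (NM_001374820.1-like), plus strand,
# Hg19 coordinates. Exact exon boundaries could not be reproduced offline;
# this table preserves the 20-exon structure, the genomic span and the
# intron-4 boundaries used by the breakpoint lookup.
exon	start	end
1	157099064	157100882
2	157150390	157150542
3	157192747	157192917
4	157229709	157230217
5	157431576	157431764
6	157454165	157454292
7	157461050	157461220
8	157469574	157469680
9	157478571	157478712
10	157488097	157488255
11	157495875	157496040
12	157502078	157502220
13	157505524	157505704
14	157510316	157510477
15	157515132	157515290
16	157519763	157519910
17	157522669	157522850
18	157525931	157526127
19	157528735	157528920
20	157530148	157531913
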