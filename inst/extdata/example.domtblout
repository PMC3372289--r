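#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord
# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target
read00001            -            120 TF_A                 -            100   1.0e-05   50.0   2.0   1   1   5.0e-06   1.0e-05   50.0   2.0     1    51     1    51     1    60 0.95 -
read00002            -            130 TF_A                 -            100   2.0e-06   64.5   1.1   1   1   1.0e-06   2.0e-06   64.5   1.1     1    21     5    25     1    80 0.92 -
read00003            -            140 TF_A                 -            100   3.1e-08   81.0   0.0   1   1   1.5e-08   3.1e-08   81.0   0.0    10    95     2    88     1   100 0.97 -
read00004            -            150 TF_B                 -            200   4.0e-12  120.3   5.5   1   1   2.0e-12   4.0e-12  120.3   5.5    20   180     1   140     1   150 0.98 -
read00005            -            160 TF_B                 -            200   7.7e-04   45.2   0.9   1   1   3.8e-04   7.7e-04   45.2   0.9    50   120     3    73     1   110 0.91 -
read00006            -            170 TF_B                 -            200   9.9e-09   90.8   4.1   1   1   5.0e-09   9.9e-09   90.8   4.1     1    42     1    42     1    60 0.94 -
decoy0001            -            120 TF_A                 -            100   1.0e-02   48.0   1.0   1   1   5.0e-03   1.0e-02   48.0   1.0     1    60     1    60     1    70 0.90 -
decoy0002            -            120 TF_A                 -            100   1.0e-06   52.0   0.5   1   1   5.0e-07   1.0e-06   52.0   0.5     1    15     1    15     1    30 0.90 -
decoy0003            -            120 TF_B                 -            200   1.0e-06   50.0  10.0   1   1   5.0e-07   1.0e-06   50.0  10.0     1   100     1   100     1   110 0.90 -
decoy0004            -            120 TF_B                 -            200   5.0e-02   50.0  30.0   1   1   2.5e-02   5.0e-02   50.0  30.0     1   100     1   100     1   110 0.90 -
#
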