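# SWC written by dendrosched
1 1 0 0 0 0.5 -1
2 3 20 0 0 0.5 1
3 3 40 0 0 0.5 2
4 3 40 0 0 0.5 2
5 3 40 0 0 0.5 2
6 3 60 0 0 0.5 3
7 3 60 0 0 0.5 5
8 3 60 0 0 0.5 4
9 3 60 0 0 0.5 5
10 3 80 0 0 0.5 6
11 3 80 0 0 0.5 8
12 3 80 0 0 0.5 7
13 3 80 0 0 0.5 9
14 3 100 0 0 0.5 12
15 3 100 0 0 0.5 13
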