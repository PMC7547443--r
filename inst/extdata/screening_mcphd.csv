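# Published MCPhd screening results: counts of predicted pairs by activity
# category at similarity thresholds 0.90/0.80/0.70. Note the published 0.70
# block is internally inconsistent: active-active (41) plus
# inactive-inactive (23) is 64 while the correct row prints 62.
threshold,category,pairs,pct
0.9,active-active,14,33
0.9,inactive-inactive,12,29
0.9,active-inactive,8,19
0.9,inactive-active,8,19
0.9,correct,26,62
0.9,incorrect,16,38
0.9,total,42,100
0.8,active-active,16,36
0.8,inactive-inactive,12,27
0.8,active-inactive,9,20
0.8,inactive-active,8,18
0.8,correct,28,62
0.8,incorrect,17,38
0.8,total,45,100
0.7,active-active,41,45
0.7,inactive-inactive,23,25
0.7,active-inactive,15,16
0.7,inactive-active,15,16
0.7,correct,62,67
0.7,incorrect,30,33
0.7,total,92,100
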