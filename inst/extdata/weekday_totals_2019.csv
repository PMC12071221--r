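weekday,weekday_index,total
Monday,1,7125
Tuesday,2,6959
Wednesday,3,6599
Thursday,4,6833
Friday,5,6812
Saturday,6,6973
Sunday,7,6734
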