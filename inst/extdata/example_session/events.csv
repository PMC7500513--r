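team_id,trial_number,player,click_time_s,click_position,target,pas
1,1,1,33.965,397.339016,other_avatar,2
1,2,2,43.414,74.150597,unknown,2
1,3,2,57.728,553.155134,other_avatar,3
1,4,1,20.62,49.218801,other_avatar,4
1,4,2,20.484,108.576682,other_avatar,1
1,5,1,35.422,467.285408,shadow,2
1,5,2,24.51,78.9135,other_avatar,1
1,6,1,3.65,525.294988,other_avatar,3
1,6,2,23.127,94.712023,other_avatar,
2,1,1,41.898,33.622166,other_avatar,4
2,1,2,17.084,589.91127,shadow,2
2,2,1,21.94,35.854553,shadow,2
2,2,2,41.828,286.782288,other_avatar,4
2,3,1,43.606,595.272302,other_avatar,4
2,4,1,55.782,59.970005,other_avatar,4
2,4,2,37.783,548.586614,other_avatar,2
2,5,1,38.701,504.200624,unknown,3
2,5,2,38.546,427.730218,other_avatar,3
2,6,1,8.609,421.753072,other_avatar,4
2,6,2,8.483,143.127396,other_avatar,4
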