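rat_id,strain,session,time_s,event_type
r01,SHR,1,12.50,correct_lever
r01,SHR,1,12.90,correct_lever
r01,SHR,1,14.10,incorrect_lever
r01,SHR,1,200.00,incorrect_door
r01,SHR,1,1079.80,correct_lever
r01,SHR,1,1080.20,correct_lever
r01,SHR,1,1081.00,reinforcer
r01,SHR,1,1082.60,correct_door
r01,SHR,1,3000.00,incorrect_door
r02,WKY,1,45.00,correct_lever
r02,WKY,1,50.25,correct_lever
r02,WKY,1,2210.00,incorrect_door
r02,WKY,1,4321.75,correct_lever
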