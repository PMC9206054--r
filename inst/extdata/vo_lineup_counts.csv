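"group","condition","lineup_type","response","confidence","count"
"young","control","target_present","suspect_id",1,0
"young","control","target_present","suspect_id",2,2
"young","control","target_present","suspect_id",3,11
"young","control","target_present","suspect_id",4,15
"young","control","target_present","suspect_id",5,43
"young","control","target_present","suspect_id",6,37
"young","control","target_present","suspect_id",7,43
"young","control","target_present","filler_id",1,2
"young","control","target_present","filler_id",2,1
"young","control","target_present","filler_id",3,2
"young","control","target_present","filler_id",4,5
"young","control","target_present","filler_id",5,10
"young","control","target_present","filler_id",6,2
"young","control","target_present","filler_id",7,1
"young","control","target_present","no_id",1,0
"young","control","target_present","no_id",2,1
"young","control","target_present","no_id",3,8
"young","control","target_present","no_id",4,12
"young","control","target_present","no_id",5,31
"young","control","target_present","no_id",6,16
"young","control","target_present","no_id",7,8
"young","control","target_absent","filler_id",1,2
"young","control","target_absent","filler_id",2,3
"young","control","target_absent","filler_id",3,21
"young","control","target_absent","filler_id",4,18
"young","control","target_absent","filler_id",5,35
"young","control","target_absent","filler_id",6,3
"young","control","target_absent","filler_id",7,2
"young","control","target_absent","no_id",1,3
"young","control","target_absent","no_id",2,5
"young","control","target_absent","no_id",3,19
"young","control","target_absent","no_id",4,24
"young","control","target_absent","no_id",5,60
"young","control","target_absent","no_id",6,34
"young","control","target_absent","no_id",7,21
"young","experimental","target_present","suspect_id",1,0
"young","experimental","target_present","suspect_id",2,2
"young","experimental","target_present","suspect_id",3,7
"young","experimental","target_present","suspect_id",4,21
"young","experimental","target_present","suspect_id",5,39
"young","experimental","target_present","suspect_id",6,27
"young","experimental","target_present","suspect_id",7,14
"young","experimental","target_present","filler_id",1,0
"young","experimental","target_present","filler_id",2,2
"young","experimental","target_present","filler_id",3,5
"young","experimental","target_present","filler_id",4,1
"young","experimental","target_present","filler_id",5,14
"young","experimental","target_present","filler_id",6,2
"young","experimental","target_present","filler_id",7,0
"young","experimental","target_present","no_id",1,2
"young","experimental","target_present","no_id",2,5
"young","experimental","target_present","no_id",3,10
"young","experimental","target_present","no_id",4,23
"young","experimental","target_present","no_id",5,40
"young","experimental","target_present","no_id",6,20
"young","experimental","target_present","no_id",7,16
"young","experimental","target_absent","filler_id",1,2
"young","experimental","target_absent","filler_id",2,6
"young","experimental","target_absent","filler_id",3,7
"young","experimental","target_absent","filler_id",4,12
"young","experimental","target_absent","filler_id",5,17
"young","experimental","target_absent","filler_id",6,3
"young","experimental","target_absent","filler_id",7,0
"young","experimental","target_absent","no_id",1,3
"young","experimental","target_absent","no_id",2,7
"young","experimental","target_absent","no_id",3,24
"young","experimental","target_absent","no_id",4,22
"young","experimental","target_absent","no_id",5,59
"young","experimental","target_absent","no_id",6,55
"young","experimental","target_absent","no_id",7,33
"older","control","target_present","suspect_id",1,0
"older","control","target_present","suspect_id",2,4
"older","control","target_present","suspect_id",3,2
"older","control","target_present","suspect_id",4,19
"older","control","target_present","suspect_id",5,35
"older","control","target_present","suspect_id",6,20
"older","control","target_present","suspect_id",7,12
"older","control","target_present","filler_id",1,2
"older","control","target_present","filler_id",2,3
"older","control","target_present","filler_id",3,3
"older","control","target_present","filler_id",4,14
"older","control","target_present","filler_id",5,18
"older","control","target_present","filler_id",6,6
"older","control","target_present","filler_id",7,0
"older","control","target_present","no_id",1,3
"older","control","target_present","no_id",2,1
"older","control","target_present","no_id",3,9
"older","control","target_present","no_id",4,22
"older","control","target_present","no_id",5,40
"older","control","target_present","no_id",6,29
"older","control","target_present","no_id",7,8
"older","control","target_absent","filler_id",1,1
"older","control","target_absent","filler_id",2,8
"older","control","target_absent","filler_id",3,10
"older","control","target_absent","filler_id",4,23
"older","control","target_absent","filler_id",5,37
"older","control","target_absent","filler_id",6,10
"older","control","target_absent","filler_id",7,2
"older","control","target_absent","no_id",1,3
"older","control","target_absent","no_id",2,5
"older","control","target_absent","no_id",3,9
"older","control","target_absent","no_id",4,27
"older","control","target_absent","no_id",5,45
"older","control","target_absent","no_id",6,47
"older","control","target_absent","no_id",7,23
"older","experimental","target_present","suspect_id",1,0
"older","experimental","target_present","suspect_id",2,1
"older","experimental","target_present","suspect_id",3,5
"older","experimental","target_present","suspect_id",4,8
"older","experimental","target_present","suspect_id",5,18
"older","experimental","target_present","suspect_id",6,11
"older","experimental","target_present","suspect_id",7,7
"older","experimental","target_present","filler_id",1,0
"older","experimental","target_present","filler_id",2,4
"older","experimental","target_present","filler_id",3,9
"older","experimental","target_present","filler_id",4,3
"older","experimental","target_present","filler_id",5,8
"older","experimental","target_present","filler_id",6,3
"older","experimental","target_present","filler_id",7,1
"older","experimental","target_present","no_id",1,3
"older","experimental","target_present","no_id",2,10
"older","experimental","target_present","no_id",3,8
"older","experimental","target_present","no_id",4,35
"older","experimental","target_present","no_id",5,48
"older","experimental","target_present","no_id",6,41
"older","experimental","target_present","no_id",7,27
"older","experimental","target_absent","filler_id",1,1
"older","experimental","target_absent","filler_id",2,4
"older","experimental","target_absent","filler_id",3,5
"older","experimental","target_absent","filler_id",4,16
"older","experimental","target_absent","filler_id",5,23
"older","experimental","target_absent","filler_id",6,4
"older","experimental","target_absent","filler_id",7,1
"older","experimental","target_absent","no_id",1,1
"older","experimental","target_absent","no_id",2,5
"older","experimental","target_absent","no_id",3,12
"older","experimental","target_absent","no_id",4,27
"older","experimental","target_absent","no_id",5,58
"older","experimental","target_absent","no_id",6,50
"older","experimental","target_absent","no_id",7,43
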