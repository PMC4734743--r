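item,code,label
last_cig,0,"I have never smoked, or even tried, a cigarette"
last_cig,1,"over 6 years ago"
last_cig,2,"over 3 years ago"
last_cig,3,"over 12 months ago"
last_cig,4,"between 6 months and 12 months ago"
last_cig,5,"between 3 months and 6 months ago"
last_cig,6,"between 1 month and 3 months ago"
last_cig,7,"8-30 days ago"
last_cig,8,"1-7 days ago"
last_cig,9,"earlier today"
freq,0,"not at all"
freq,1,"less than once a month"
freq,2,"once a month or more, but less than once a week"
freq,3,"once a week or more, but not daily"
freq,4,"at least daily"
days30,0,"0 days"
days30,1,"1 day"
days30,2,"2-4 days"
days30,3,"5-9 days"
days30,4,"10-19 days"
days30,5,"20-29 days"
days30,6,"every day"
smoked30,0,"no"
smoked30,1,"yes"
quit_attempt,0,"none"
quit_attempt,1,"one or more"
quit_len,0,"no quit attempt"
quit_len,1,"less than 1 day"
quit_len,2,"1-7 days"
quit_len,3,"8-30 days"
quit_len,4,"1-6 months"
quit_len,5,"more than 6 months"
stage,1,"precontemplation"
stage,2,"contemplation"
stage,3,"preparation"
ladder,0,"0 - no thought of quitting"
ladder,1,"1"
ladder,2,"2"
ladder,3,"3"
ladder,4,"4"
ladder,5,"5"
ladder,6,"6"
ladder,7,"7"
ladder,8,"8"
ladder,9,"9"
ladder,10,"10 - taking action to quit"
cigs_day,0,"none"
cigs_day,1,"less than 1 per day"
cigs_day,2,"1-5 per day"
cigs_day,3,"6-10 per day"
cigs_day,4,"11-20 per day"
cigs_day,5,"more than 20 per day"
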