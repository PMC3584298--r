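study,species,time_scale,task,lesion,n_points,mu1,mu2,a1,r_squared,mtl_lifetime_days
Cho et al. 1993,mouse,3.5-56 days,two-choice spatial discrimination,EC,8,1.50,0.00325,0.103,0.94,9.7
Cho & Kesner 1996,rat,3.5-42 days,spatial discrimination,EC,8,1.60,0.0146,0.0249,0.97,40.2
Kim & Fanselow 1992,rat,3.5-56 days,contextual fear conditioning,H,8,1.07,0.0149,0.0279,0.93,35.9
Wiig et al. 1996,rat,7-56 days,visual discrimination,F,5,NA,0.00798,0.0335,0.94,29.9
Winocur 1990,rat,0-10 days,socially acquired food preference,DH,8,1.21,0.124,0.286,0.88,3.5
Zola-Morgan & Squire 1990,monkey,14-112 days,delayed matching to stimulus,H,10,1.78,0.0116,0.0446,0.71,22.4
Frankland et al. 2001,mouse,1-50 days,contextual fear conditioning,NC,23,0.372,0.519,0.326,0.98,3.1
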