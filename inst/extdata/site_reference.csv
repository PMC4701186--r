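site,population,n_chw,period_start_cmc,period_end_cmc,months,total_cost_usd,cost_per_1000_printed,cost_per_event_printed,pct_reporting,completeness_births,completeness_under5_deaths,ratio_nmr,ratio_imr,ratio_u5mr
ethiopia,509395,183,1345,1359,15,444392,523,72,95.7,30.1,21.7,89.0,81.0,72.0
malawi,203741,160,1321,1368,48,353782,434,21,96.6,65.9,50.6,74.0,67.5,67.7
mali,32128,78,1351,1365,15,288766,6344,149,100,90.3,90.8,128.8,120.0,100.6
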