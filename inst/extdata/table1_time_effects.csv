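study_id,group,tracer_target,region,index,r,t,df,n,exclude,note
raclopride_gambling,addiction,d2_receptor,ventral_striatum,k,-0.700,,,12,FALSE,pathological gambling; baseline D2R availability
raclopride_gambling,healthy,d2_receptor,ventral_striatum,k,-0.010,,,12,FALSE,matched healthy controls; baseline D2R availability
raclopride_gambling,addiction,d2_receptor,ventral_striatum,k,-0.890,,,12,FALSE,pathological gambling; DA release measure
raclopride_gambling,healthy,d2_receptor,ventral_striatum,k,0.150,,,12,FALSE,matched healthy controls; DA release measure
raclopride_gambling,other_psychopathology,da_synthesis,caudate,k,0.640,,,17,FALSE,Parkinson's disease; FDOPA synthesis capacity
fallypride_meth,addiction,d2_receptor,whole_striatum,ln_k,-0.342,,,27,FALSE,methamphetamine users; baseline D2R availability
fallypride_meth,healthy,d2_receptor,whole_striatum,ln_k,-0.179,,,27,FALSE,matched healthy controls
raclopride_alcohol,addiction,d2_receptor,ventral_striatum,auc,0.650,,,10,FALSE,non-treatment-seeking alcohol users; peak voxelwise statistic
raclopride_alcohol,healthy,d2_receptor,ventral_striatum,auc,0.611,,,11,FALSE,social drinkers serving as controls; peak voxelwise statistic
nmb_obesity,other_psychopathology,d2_receptor,whole_striatum,auc,-0.560,,,23,FALSE,obesity; partial correlation as reported
nmb_obesity,healthy,d2_receptor,whole_striatum,auc,0.050,,,19,FALSE,matched healthy controls; partial correlation as reported
fmt_healthy,healthy,da_synthesis,putamen,proportion_smaller,-0.513,,,16,FALSE,healthy adults; Spearman rho treated as r
fpcit_adhd,other_psychopathology,dat,putamen,occupancy_correlate,-0.536,,,24,FALSE,treatment-naive ADHD; methylphenidate occupancy inversely related to DAT availability
phno_healthy,healthy,d2_receptor,pallidum,ln_k,,,,11,TRUE,quadratic association only; no linear correlation reported
present_study,healthy,d2_receptor,whole_striatum,proportion_smaller,0.027,,,109,FALSE,partial correlation controlling age sex and sample; whole-striatum D2R availability
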