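sample_id,site,marker,compartment,area_mm2,count,method
subj1,sigmoid,CD3,combined,1,489,manual
subj1,sigmoid,CD3,combined,1,494,manual
subj1,sigmoid,CD3,combined,1,499,manual
subj1,sigmoid,CD3,combined,1,510,automated
subj1,sigmoid,CD3,combined,1,504,automated
subj1,sigmoid,CD3,combined,1,523,automated
subj2,sigmoid,CD3,combined,1,493,manual
subj2,sigmoid,CD3,combined,1,498,manual
subj2,sigmoid,CD3,combined,1,503,manual
subj2,sigmoid,CD3,combined,1,514,automated
subj2,sigmoid,CD3,combined,1,508,automated
subj2,sigmoid,CD3,combined,1,527,automated
subj3,sigmoid,CD3,combined,1,497,manual
subj3,sigmoid,CD3,combined,1,502,manual
subj3,sigmoid,CD3,combined,1,507,manual
subj3,sigmoid,CD3,combined,1,518,automated
subj3,sigmoid,CD3,combined,1,512,automated
subj3,sigmoid,CD3,combined,1,531,automated
subj4,sigmoid,CD3,combined,1,501,manual
subj4,sigmoid,CD3,combined,1,506,manual
subj4,sigmoid,CD3,combined,1,511,manual
subj4,sigmoid,CD3,combined,1,522,automated
subj4,sigmoid,CD3,combined,1,516,automated
subj4,sigmoid,CD3,combined,1,536,automated
subj5,sigmoid,CD3,combined,1,505,manual
subj5,sigmoid,CD3,combined,1,510,manual
subj5,sigmoid,CD3,combined,1,515,manual
subj5,sigmoid,CD3,combined,1,526,automated
subj5,sigmoid,CD3,combined,1,520,automated
subj5,sigmoid,CD3,combined,1,540,automated
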