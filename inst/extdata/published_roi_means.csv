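study,subject,region,roi_nc,roi_ac_ct,roi_ac_se,rv_ct_printed,rv_se_printed
uniform-phantom,mouse,center,429.68,623.02,613.89,31.0,29.6
uniform-phantom,rat,center,210.34,405.32,396.17,48.1,45.8
hot-sphere-phantom,rat,sphere,452.79,760.83,708.37,40.5,33.6
fdg-tumour,mouse,tumour,527.82,716.94,726.13,26.4,27.7
fdg-cardiac,mouse,myocardium,3463.70,4478.60,4393.40,22.7,20.8
fdg-cardiac,mouse,ventricle,1975.00,2577.30,2511.30,23.4,20.8
fdg-cardiac,rat,myocardium,520.35,858.38,785.43,39.4,30.9
fdg-cardiac,rat,ventricle,352.63,589.99,537.87,40.2,31.4
acetate-liver,rat,liver,174.92,327.04,291.56,46.5,35.7
ga-chloride-kidney,rat,kidney,245.45,459.14,427.37,46.5,39.6
naf-spine,rat,spine,419.70,770.14,623.67,45.5,26.5
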