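"article_id","journal","year","confound_label","report_kind","value","decimals"
"A0001","synthetic","2001","confound_1","exact","0.65","2"
"A0001","synthetic","2001","confound_2","bound_greater","0.05",""
"A0002","synthetic","2002","confound_1","exact","0.62","2"
"A0002","synthetic","2002","confound_2","exact","0.32","2"
"A0002","synthetic","2002","confound_3","exact","0.90","2"
"A0003","synthetic","2003","confound_1","exact","0.79","2"
"A0004","synthetic","2004","confound_1","exact","0.43","2"
"A0004","synthetic","2004","confound_2","exact","0.76","2"
"A0004","synthetic","2004","confound_3","exact","0.74","2"
"A0004","synthetic","2004","confound_4","exact","0.54","2"
"A0005","synthetic","2005","confound_1","bound_greater","0.05",""
"A0005","synthetic","2005","confound_2","exact","0.94","2"
"A0005","synthetic","2005","confound_3","exact","0.92","2"
"A0005","synthetic","2005","confound_5","exact","0.20","2"
"A0006","synthetic","2006","confound_1","exact","0.09","2"
"A0006","synthetic","2006","confound_2","exact","0.58","2"
"A0007","synthetic","2007","confound_1","exact","0.74","2"
"A0008","synthetic","2008","confound_1","bound_greater","0.05",""
"A0009","synthetic","2009","confound_1","exact","0.94","2"
"A0010","synthetic","2010","confound_1","exact","0.30","2"
"A0011","synthetic","2011","confound_1","exact","0.13","2"
"A0011","synthetic","2011","confound_2","exact","0.48","2"
"A0011","synthetic","2011","confound_3","bound_greater","0.05",""
"A0012","synthetic","2012","confound_1","exact","0.35","2"
"A0013","synthetic","2013","confound_1","exact","0.64","2"
"A0014","synthetic","2014","confound_1","exact","0.52","2"
"A0014","synthetic","2014","confound_2","exact","0.91","2"
"A0015","synthetic","2015","confound_1","exact","0.35","2"
"A0015","synthetic","2015","confound_2","bound_greater","0.05",""
"A0015","synthetic","2015","confound_3","exact","0.34","2"
"A0015","synthetic","2015","confound_4","qualitative_ns","",""
"A0015","synthetic","2015","confound_5","bound_greater","0.05",""
"A0015","synthetic","2015","confound_6","exact","0.58","2"
"A0015","synthetic","2015","confound_7","exact","0.68","2"
"A0016","synthetic","2016","confound_1","exact","0.41","2"
"A0017","synthetic","2017","confound_1","exact","0.02","2"
"A0018","synthetic","2018","confound_1","exact","0.30","2"
"A0018","synthetic","2018","confound_2","exact","0.03","2"
"A0018","synthetic","2018","confound_3","exact","0.68","2"
"A0018","synthetic","2018","confound_4","exact","0.14","2"
"A0018","synthetic","2018","confound_5","exact","0.60","2"
"A0018","synthetic","2018","confound_6","exact","0.56","2"
"A0018","synthetic","2018","confound_7","bound_greater","0.05",""
"A0019","synthetic","2000","confound_1","exact","0.30","2"
"A0019","synthetic","2000","confound_2","exact","0.60","2"
"A0020","synthetic","2001","confound_1","exact","0.43","2"
"A0021","synthetic","2002","confound_1","bound_greater","0.05",""
"A0022","synthetic","2003","confound_1","exact","0.89","2"
"A0022","synthetic","2003","confound_2","qualitative_ns","",""
"A0023","synthetic","2004","confound_1","exact","0.78","2"
"A0023","synthetic","2004","confound_2","exact","0.62","2"
"A0024","synthetic","2005","confound_1","exact","0.58","2"
"A0025","synthetic","2006","confound_1","bound_greater","0.05",""
"A0026","synthetic","2007","confound_1","bound_greater","0.05",""
"A0027","synthetic","2008","confound_1","bound_greater","0.05",""
"A0027","synthetic","2008","confound_2","exact","0.52","2"
"A0027","synthetic","2008","confound_3","exact","0.41","2"
"A0028","synthetic","2009","confound_1","exact","0.16","2"
"A0029","synthetic","2010","confound_1","exact","0.22","2"
"A0029","synthetic","2010","confound_2","exact","0.11","2"
"A0029","synthetic","2010","confound_3","exact","0.65","2"
"A0030","synthetic","2011","confound_1","exact","0.91","2"
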