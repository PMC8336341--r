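patient_id,ancestry,collection_date,last_visit_date,death_date,age,psa,gleason_primary,gleason_secondary,stage,metastasis,nccn_printed,glycb_rank,metabotype,note
SAPC0159,Black,2017/03/01,2017/03/23,,75.2,>5000,5,5,T3/T4,TRUE,Metastatic,3,IV,
SAPC0090,Colored,2015/05/08,2015/06/27,,78.2,6.3,3,3,T1c,FALSE,Low,8,IV,pancreatic cancer diagnosed 19 days after collection
SAPC0192,Colored,2017/07/31,2017/12/19,,80.9,41.68,4,5,T2a,FALSE,Very high,7,III,died of bone metastasis 5 months after collection
SAPC0080,Black,2014/10/31,2015/04/21,,77.8,738,3,5,T4,FALSE,Very high,2,IV,
SAPC0180,Black,2017/06/23,2017/12/12,,58.1,>5000,5,5,T3/T4,FALSE,Very high,1,IV,
SAPC0249,Colored,2018/03/25,2019/01/07,,63,1070,5,4,T3,FALSE,Very high,4,IV,
SAPC0078,White,2014/11/07,2015/10/31,,74.3,135.79,5,5,T4,FALSE,Very high,5,IV,
SAPC0193,Colored,2017/08/11,2019/04/26,,63.5,48.85,3,4,T3,FALSE,Very high,9,III,
SAPC0070,Colored,2014/01/08,2015/12/11,,65.4,34.8,4,5,T2b,FALSE,Very high,13,II,
SAPC0191,White,2017/07/28,2019/08/03,,61.8,576,5,4,T3,FALSE,Very high,6,IV,
SAPC0195,Black,2017/08/13,2020/01/30,,87.2,26.53,4,5,T3,FALSE,Very high,11,III,
SAPC0120,Black,2016/10/03,2019/09/30,,82.3,289.9,4,5,T3,FALSE,Very high,14,II,
SAPC0108,Colored,2016/06/27,2020/04/17,,56.6,96.3,3,4,T4,FALSE,Very high,12,III,
SAPC0076,Colored,2014/09/26,2020/06/04,,63.5,140.42,3,4,T3/T4,FALSE,Very high,10,III,
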