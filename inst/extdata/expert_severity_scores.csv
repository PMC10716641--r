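subject_id,cee_date,cee_type,behavioural_state,prey_pre,prey_post,csel_db,change,confidence,severity_score,change_description
20160914_B020-BP,2016-09-16,CONTROL,deep-feeding,no,no,NA,no,med,NA,
bp10_236a,2010-08-24,MFAS,deep-feeding,no,no,160,no,high,NA,
bp10_239a,2010-08-27,MFAS,deep-feeding,no,no,145,yes,med,2,brief changes in respiration rate; minor change in dive profile
bp13_216a,2013-08-04,MFAS,deep-feeding,yes,yes,153,no,med,NA,
bp16_256a,2016-09-12,MFAS,deep-feeding,yes,yes,162,no,med,NA,
20160912_B014-BP,2016-09-12,MFAS,deep-feeding,no,no,164,no,med,NA,
bp10_245a,2010-09-02,PRN,deep-feeding,no,no,166,no,med,NA,
bp10_247a,2010-09-04,PRN,deep-feeding,no,no,111,yes,high,6,moderate cessation in feeding; minor avoidance of source (5)
bp12_217a,2012-08-04,PRN,deep-feeding,yes,yes,153,no,high,NA,
bp13_258a,2013-09-15,CONTROL,shallow-feeding,yes,yes,NA,no,med,NA,
bp13_258b,2013-09-15,CONTROL,shallow-feeding,yes,yes,NA,no,high,NA,
bp13_258c,2013-09-15,CONTROL,shallow-feeding,yes,yes,NA,no,low,NA,
bp13_265a,2013-09-22,CONTROL,shallow-feeding,no,no,NA,no,med,NA,no change identified according to specified criteria but groups noted onset of foraging during CEE
bp13_257b,2013-09-14,MFAS,shallow-feeding,yes,no,105,yes,low,4,minor avoidance of source
bp13_259a,2013-09-16,MFAS,shallow-feeding,yes,yes,156,no,med,NA,
bp15_236a,2015-08-24,MFAS,shallow-feeding,yes,yes,156,no,high,NA,
bp14_259a,2014-09-16,CONTROL,non-feeding,yes,yes,NA,no,med,NA,
bp10_236b,2010-08-24,MFAS,non-feeding,no,no,129,yes,med,4,minor avoidance of source
bp13_139a,2013-05-19,MFAS,non-feeding,no,no,149,no,med,NA,
bp15_229a,2015-08-17,MFAS,non-feeding,yes,no,151,no,high,NA,
bp12_294a,2012-10-20,PRN,non-feeding,yes,yes,101,yes,high,NA,moderate change in diving behaviour
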