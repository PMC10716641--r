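subject_id,cee_date,cee_id,cee_type,behavioural_state,pre_start,exposure_start,exposure_min,post_start,prey_mapping
20160914_B020-BP,2016-09-16,2016_04,CONTROL,deep-feeding,1323,1353,30,1423,no
bp10_236a,2010-08-24,2010_03,MFAS,deep-feeding,1120,1150,30,1220,no
bp10_239a,2010-08-27,2010_05,MFAS,deep-feeding,1204,1234,30,1304,no
bp13_216a,2013-08-04,2013_11,MFAS,deep-feeding,1539,1609,19,1628,yes
bp16_256a,2016-09-12,2016_03,MFAS,deep-feeding,1512,1542,30,1612,yes
20160912_B014-BP,2016-09-12,2016_03,MFAS,deep-feeding,1512,1542,30,1612,no
bp10_245a,2010-09-02,2010_11,PRN,deep-feeding,1322,1352,30,1422,no
bp10_247a,2010-09-04,2010_13,PRN,deep-feeding,1314,1344,30,1414,no
bp12_217a,2012-08-04,2012_03,PRN,deep-feeding,1422,1452,30,1522,yes
bp13_258a,2013-09-15,2013_15,CONTROL,shallow-feeding,1252,1322,30,1352,yes
bp13_258b,2013-09-15,2013_15,CONTROL,shallow-feeding,1252,1322,30,1352,yes
bp13_258c,2013-09-15,2013_15,CONTROL,shallow-feeding,1252,1322,30,1352,no
bp13_265a,2013-09-22,2013_19,CONTROL,shallow-feeding,1312,1342,30,1412,no
bp13_257b,2013-09-14,2013_14,MFAS,shallow-feeding,1530,1600,30,1630,yes
bp13_259a,2013-09-16,2013_16,MFAS,shallow-feeding,1046,1116,30,1146,yes
bp15_236a,2015-08-24,2015_06,MFAS,shallow-feeding,1357,1427,30,1457,yes
bp14_259a,2014-09-16,2014_08,CONTROL,non-feeding,1322,1352,30,1422,yes
bp10_236b,2010-08-24,2010_03,MFAS,non-feeding,1120,1150,30,1220,no
bp13_139a,2013-05-19,2013_01,MFAS,non-feeding,0944,1014,30,1044,no
bp15_229a,2015-08-17,2015_02,MFAS,non-feeding,1211,1241,30,1311,yes
bp12_294a,2012-10-20,2012_06,PRN,non-feeding,1416,1446,30,1516,yes
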