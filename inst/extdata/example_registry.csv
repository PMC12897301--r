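case_id,diagnosis_date,diagnosis_year,age_group,sex,iccc_code,behaviour,morphology,microscopically_verified,sequence_number,vital_status,followup_end_date
S000001,1999-01-22,1999,5-9,male,IVa,malignant,9500,true,1,dead,1999-08-07
S000002,1999-01-20,1999,10-14,male,Ia,malignant,9835,true,1,dead,2002-07-28
S000003,2000-12-05,2000,<1,male,Ia,malignant,9835,true,1,alive,2022-12-31
S000004,2000-04-03,2000,10-14,male,XIb,malignant,8330,true,1,alive,2022-12-31
S000005,2001-11-17,2001,1-4,female,Xc,malignant,9085,true,1,lost,2011-10-14
S000006,2001-05-22,2001,1-4,female,IVa,malignant,9500,true,1,lost,2017-10-29
S000007,2001-04-14,2001,10-14,male,IIa,malignant,9650,true,1,alive,2022-12-31
S000008,2002-11-02,2002,1-4,male,Ia,malignant,9835,true,1,alive,2022-12-31
S000009,2002-12-28,2002,5-9,male,IXa,malignant,8900,true,1,dead,2014-03-09
S000010,2002-07-07,2002,5-9,male,IIIa,malignant,9391,false,1,alive,2022-12-31
S000011,2002-04-11,2002,10-14,female,IIIa,malignant,9391,true,1,alive,2022-12-31
S000012,2004-05-26,2004,1-4,male,VIIIa,malignant,9180,true,1,alive,2022-12-31
S000013,2004-02-19,2004,1-4,male,IIIb,non_malignant,9400,true,1,alive,2022-12-31
S000014,2004-05-13,2004,1-4,female,VIa,malignant,8960,true,2,alive,2022-12-31
S000015,2004-07-25,2004,1-4,female,Ib,malignant,9861,true,1,dead,2006-12-09
S000016,2005-03-10,2005,1-4,female,VIIIa,malignant,9180,true,1,dead,2006-04-10
S000017,2005-07-29,2005,1-4,female,IIIc,malignant,9470,true,1,dead,2005-12-12
S000018,2005-03-15,2005,5-9,female,IIa,malignant,9650,true,1,dead,2006-07-15
S000019,2006-05-31,2006,1-4,female,IIIb,non_malignant,9400,true,1,dead,2021-10-12
S000020,2006-06-24,2006,5-9,male,Ia,malignant,9835,true,1,alive,2022-12-31
S000021,2006-03-31,2006,5-9,female,Ib,malignant,9861,true,1,alive,2022-12-31
S000022,2007-12-01,2007,<1,female,IIa,malignant,9650,true,1,dead,2009-10-25
S000023,2007-12-04,2007,1-4,male,XIa,malignant,8010,true,1,alive,2022-12-31
S000024,2008-12-17,2008,<1,male,IIIb,non_malignant,9400,false,1,alive,2022-12-31
S000025,2008-08-25,2008,1-4,male,VIa,malignant,8960,true,1,alive,2022-12-31
S000026,2008-09-25,2008,5-9,male,IVa,malignant,9500,false,1,alive,2022-12-31
S000027,2008-05-17,2008,5-9,male,IId,malignant,9750,true,1,alive,2022-12-31
S000028,2009-10-25,2009,1-4,female,IVa,malignant,9500,true,1,alive,2022-12-31
S000029,2009-01-08,2009,1-4,male,IIIf,malignant,8000,true,1,alive,2022-12-31
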