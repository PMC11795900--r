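"study_id","outcome_id","assessor_id","design","question_id","answer","justification"
"S1","O1","A1","controlled","D1.Q1","no",
"S1","O1","A1","controlled","D1.Q2","no_information",
"S1","O1","A1","controlled","D1.Q3","yes",
"S1","O1","A1","controlled","D1.Q4","yes",
"S1","O1","A1","controlled","D1.Q5","yes",
"S1","O1","A1","controlled","D2.Q1","yes",
"S1","O1","A1","controlled","D2.Q2","yes",
"S1","O1","A1","controlled","D2.Q3","yes",
"S1","O1","A1","controlled","D2.Q4","no",
"S1","O1","A1","controlled","D2.Q5","yes",
"S1","O1","A1","controlled","D3.Q1","yes",
"S1","O1","A1","controlled","D3.Q2","yes",
"S1","O1","A1","controlled","D3.Q3","yes",
"S1","O1","A1","controlled","D3.Q4","yes",
"S2","O1","A1","controlled","D1.Q1","yes",
"S2","O1","A1","controlled","D1.Q2","no",
"S2","O1","A1","controlled","D1.Q3","yes",
"S2","O1","A1","controlled","D1.Q4","yes",
"S2","O1","A1","controlled","D1.Q5","yes",
"S2","O1","A1","controlled","D2.Q1","yes",
"S2","O1","A1","controlled","D2.Q2","no_information",
"S2","O1","A1","controlled","D2.Q3","yes",
"S2","O1","A1","controlled","D2.Q4","no",
"S2","O1","A1","controlled","D2.Q5","yes",
"S2","O1","A1","controlled","D3.Q1","yes",
"S2","O1","A1","controlled","D3.Q2","yes",
"S2","O1","A1","controlled","D3.Q3","yes",
"S2","O1","A1","controlled","D3.Q4","no",
"S3","O1","A1","controlled","D1.Q1","yes",
"S3","O1","A1","controlled","D1.Q2","yes",
"S3","O1","A1","controlled","D1.Q3","yes",
"S3","O1","A1","controlled","D1.Q4","no_information",
"S3","O1","A1","controlled","D1.Q5","yes",
"S3","O1","A1","controlled","D2.Q1","yes",
"S3","O1","A1","controlled","D2.Q2","yes",
"S3","O1","A1","controlled","D2.Q3","yes",
"S3","O1","A1","controlled","D2.Q4","no",
"S3","O1","A1","controlled","D2.Q5","no_information",
"S3","O1","A1","controlled","D3.Q1","yes",
"S3","O1","A1","controlled","D3.Q2","yes",
"S3","O1","A1","controlled","D3.Q3","yes",
"S3","O1","A1","controlled","D3.Q4","yes",
"S4","O1","A1","controlled","D1.Q1","yes",
"S4","O1","A1","controlled","D1.Q2","no",
"S4","O1","A1","controlled","D1.Q3","yes",
"S4","O1","A1","controlled","D1.Q4","yes",
"S4","O1","A1","controlled","D1.Q5","yes",
"S4","O1","A1","controlled","D2.Q1","yes",
"S4","O1","A1","controlled","D2.Q2","yes",
"S4","O1","A1","controlled","D2.Q3","yes",
"S4","O1","A1","controlled","D2.Q4","yes",
"S4","O1","A1","controlled","D2.Q5","yes",
"S4","O1","A1","controlled","D3.Q1","yes",
"S4","O1","A1","controlled","D3.Q2","no",
"S4","O1","A1","controlled","D3.Q3","yes",
"S4","O1","A1","controlled","D3.Q4","no",
"S5","O1","A1","controlled","D1.Q1","yes",
"S5","O1","A1","controlled","D1.Q2","yes",
"S5","O1","A1","controlled","D1.Q3","yes",
"S5","O1","A1","controlled","D1.Q4","yes",
"S5","O1","A1","controlled","D1.Q5","yes",
"S5","O1","A1","controlled","D2.Q1","yes",
"S5","O1","A1","controlled","D2.Q2","yes",
"S5","O1","A1","controlled","D2.Q3","yes",
"S5","O1","A1","controlled","D2.Q4","no_information",
"S5","O1","A1","controlled","D2.Q5","yes",
"S5","O1","A1","controlled","D3.Q1","yes",
"S5","O1","A1","controlled","D3.Q2","yes",
"S5","O1","A1","controlled","D3.Q3","yes",
"S5","O1","A1","controlled","D3.Q4","yes",
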