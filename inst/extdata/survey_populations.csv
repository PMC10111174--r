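site_code,latitude,longitude,n,N_A,P_A,H_O,H_E,F_IS,sample_year,cluster_id
Vuo,60d31m,21d15m,4,26,1,0.23,0.25,0.34,2012,V
Nad,60d28m,22d01m,22,32,0,0.17,0.20,0.35,2012,V
Bla,59d59m,18d16m,28,30,1,0.19,0.25,0.39,2012,IV
Ham,59d46m,17d35m,21,48,4,0.32,0.47,0.36,2012,IV
Tul42,58d59m,17d33m,30,74,6,0.45,0.57,0.32,2012,III
Tul3,58d58m,17d37m,27,65,1,0.33,0.44,0.37,2012,III
Tul11,58d58m,17d37m,24,60,0,0.39,0.50,0.31,2012,III
Get,58d40m,16d19m,26,70,4,0.42,0.55,0.34,2012,III
Ver,57d44m,16d31m,34,81,3,0.40,0.58,0.37,2012,II
Em,57d08m,16d29m,28,77,4,0.51,0.61,0.30,2012,II
Res,56d32m,16d31m,27,89,14,0.47,0.61,0.33,2012,II
Vad,56d26m,12d34m,4,21,2,NA,0.44,0.35,1991,NA
Hal,56d10m,15d50m,19,53,2,0.34,0.43,0.31,2012,I
Lis,56d02m,14d47m,24,43,2,0.29,0.43,0.40,2012,I
Sol,55d56m,11d55m,5,24,1,NA,0.56,0.60,1991,NA
Ror,55d56m,11d46m,6,35,1,0.26,0.35,0.35,1991,NA
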