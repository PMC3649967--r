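code	description
MP:SYN0001	synthetic prenatal lethality subclass 1
MP:SYN0002	synthetic prenatal lethality subclass 2
MP:SYN0003	synthetic prenatal lethality subclass 3
MP:SYN0004	synthetic prenatal lethality subclass 4
MP:SYN0005	synthetic prenatal lethality subclass 5
MP:SYN0006	synthetic prenatal lethality subclass 6
MP:SYN0007	synthetic prenatal lethality subclass 7
MP:SYN0008	synthetic prenatal lethality subclass 8
MP:SYN0009	synthetic prenatal lethality subclass 9
MP:SYN0010	synthetic prenatal lethality subclass 10
MP:SYN0011	synthetic prenatal lethality subclass 11
MP:SYN0012	synthetic prenatal lethality subclass 12
MP:SYN0013	synthetic prenatal lethality subclass 13
MP:SYN0014	synthetic prenatal lethality subclass 14
MP:SYN0015	synthetic prenatal lethality subclass 15
MP:SYN0016	synthetic prenatal lethality subclass 16
MP:SYN0017	synthetic prenatal lethality subclass 17
MP:SYN0018	synthetic prenatal lethality subclass 18
MP:SYN0019	synthetic prenatal lethality subclass 19
MP:SYN0020	synthetic prenatal lethality subclass 20
MP:SYN0021	synthetic perinatal lethality subclass 1
MP:SYN0022	synthetic perinatal lethality subclass 2
MP:SYN0023	synthetic perinatal lethality subclass 3
MP:SYN0024	synthetic perinatal lethality subclass 4
MP:SYN0025	synthetic perinatal lethality subclass 5
MP:SYN0026	synthetic perinatal lethality subclass 6
MP:SYN0027	synthetic perinatal lethality subclass 7
MP:SYN0028	synthetic perinatal lethality subclass 8
MP:SYN0029	synthetic perinatal lethality subclass 9
MP:SYN0030	synthetic perinatal lethality subclass 10
MP:SYN0031	synthetic perinatal lethality subclass 11
MP:SYN0032	synthetic perinatal lethality subclass 12
MP:SYN0033	synthetic perinatal lethality subclass 13
MP:SYN0034	synthetic postnatal lethality subclass 1
MP:SYN0035	synthetic postnatal lethality subclass 2
MP:SYN0036	synthetic postnatal lethality subclass 3
MP:SYN0037	synthetic postnatal lethality subclass 4
MP:SYN0038	synthetic postnatal lethality subclass 5
MP:SYN0039	synthetic postnatal lethality subclass 6
MP:SYN0040	synthetic postnatal lethality subclass 7
MP:SYN0041	synthetic postnatal lethality subclass 8
MP:SYN0042	synthetic postnatal lethality subclass 9
MP:SYN0043	synthetic postnatal lethality subclass 10
MP:SYN0044	synthetic postnatal lethality subclass 11
MP:SYN0045	synthetic postnatal lethality subclass 12
MP:SYN0046	synthetic postnatal lethality subclass 13
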