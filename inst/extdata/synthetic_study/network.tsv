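#from	to
g0001	g0002
g0001	g0003
g0001	g0004
g0001	g0005
g0001	g0010
g0001	g0023
g0001	g0040
g0001	g0061
g0002	g0003
g0002	g0005
g0002	g0006
g0002	g0007
g0002	g0008
g0002	g0012
g0002	g0013
g0002	g0017
g0002	g0018
g0002	g0020
g0002	g0039
g0002	g0046
g0002	g0054
g0002	g0065
g0002	g0068
g0002	g0071
g0002	g0072
g0002	g0075
g0003	g0006
g0003	g0007
g0003	g0008
g0003	g0009
g0003	g0011
g0003	g0012
g0003	g0013
g0003	g0017
g0003	g0018
g0003	g0020
g0003	g0022
g0003	g0024
g0003	g0025
g0003	g0026
g0003	g0027
g0003	g0031
g0003	g0032
g0003	g0033
g0003	g0036
g0003	g0037
g0003	g0040
g0003	g0042
g0003	g0045
g0003	g0052
g0003	g0054
g0003	g0055
g0003	g0058
g0003	g0060
g0003	g0062
g0003	g0064
g0003	g0066
g0003	g0067
g0003	g0075
g0003	g0077
g0003	g0080
g0004	g0037
g0005	g0018
g0005	g0021
g0006	g0009
g0006	g0012
g0006	g0016
g0006	g0018
g0006	g0029
g0006	g0035
g0006	g0036
g0006	g0039
g0006	g0045
g0006	g0080
g0007	g0013
g0007	g0018
g0007	g0026
g0007	g0038
g0007	g0047
g0007	g0049
g0007	g0050
g0007	g0051
g0007	g0063
g0007	g0067
g0007	g0073
g0008	g0012
g0008	g0037
g0008	g0046
g0008	g0057
g0008	g0062
g0009	g0013
g0009	g0014
g0009	g0025
g0009	g0039
g0009	g0047
g0009	g0072
g0010	g0012
g0011	g0026
g0011	g0028
g0011	g0030
g0011	g0034
g0011	g0062
g0012	g0031
g0012	g0035
g0012	g0037
g0012	g0068
g0012	g0076
g0013	g0046
g0013	g0059
g0013	g0068
g0013	g0074
g0014	g0015
g0014	g0067
g0017	g0037
g0018	g0019
g0018	g0023
g0018	g0037
g0018	g0044
g0018	g0052
g0018	g0055
g0018	g0056
g0018	g0066
g0018	g0076
g0018	g0078
g0019	g0020
g0019	g0027
g0019	g0043
g0020	g0048
g0022	g0037
g0023	g0067
g0025	g0032
g0026	g0031
g0027	g0071
g0029	g0038
g0030	g0058
g0030	g0067
g0030	g0076
g0031	g0053
g0031	g0075
g0032	g0047
g0032	g0062
g0032	g0064
g0034	g0045
g0034	g0072
g0035	g0039
g0036	g0039
g0037	g0044
g0037	g0053
g0037	g0077
g0039	g0041
g0039	g0046
g0039	g0048
g0039	g0061
g0040	g0069
g0045	g0078
g0046	g0078
g0048	g0051
g0048	g0055
g0052	g0079
g0055	g0070
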