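SYN001  1950   191   187   139   178   214   103    97   198   119   262
SYN001  1960   235   196   144   135   157    88    91    84    66    90
SYN001  1970   181    99    79    61   129   189   137   101   136   168
SYN001  1980   114   105    75   103    66   131   124    70   154   142
SYN001  1990    88   116    82   145    93   133   161   114    96   113
SYN001  2000   156    69   349    59    78   168    54    59    52   999
SYN002  1941   194   274   136   189   137    98   158   100   204
SYN002  1950   140   194    59    91   175    88    74   178    81   165
SYN002  1960   130   106   142    95   128    72    70    56   132    78
SYN002  1970   178    81    97    57    46   156    99    99   127    96
SYN002  1980   122   102    32    86    63   137    70    87    71    82
SYN002  1990    95   116    89    57    66   163    91    97    79    79
SYN002  2000    79    71   118    39    70   131    47    57    87   999
SYN003  1950   137   130    49   107   258   102    81   169    97   170
SYN003  1960   235   143   312   170   142    66    62    97   110    72
SYN003  1970   365    88   100    39    64   233   115   106   162   113
SYN003  1980   209    96    37   130    66   161   104   116    85   114
SYN003  1990   118   196    64    60    70    99    69   103    88    57
SYN003  2000    55   107   122    58   111   157    67    91   106   999
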