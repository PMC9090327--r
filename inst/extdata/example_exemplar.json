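{"id":"E1","category":1,"points":[[90.3403827333278,0],[92.1056623213907,11.4216796948575],[94.1481490803853,22.7984835664953],[95.7378068356893,34.245052477434],[96.2424062376571,45.786052476988],[95.1407736235598,57.2797914484427],[92.0067600225562,68.3857739092451],[86.5704439354689,78.5568987579654],[80.807192582944,88.2235804457101],[82.4837410247815,99.63897152723],[84.5091538924402,111.015415351177],[84.0461187788225,122.473407627482],[74.6257586076923,126.305711699431],[64.5737310784657,120.69839606128],[55.6700888853735,113.335108723953],[47.1806856304027,105.490911455485],[37.9859519782548,98.5819182077191],[26.6300285918515,96.4907695110206],[15.496072412965,93.3974546739312],[4.51949783036238,89.7757278082487],[-6.56252063400163,86.5004731803644],[-17.9273766656444,84.4341710233467],[-29.4471340293585,83.5085698319873],[-40.9765315982146,82.69683113185],[-52.398288602244,80.9662753811838],[-63.4378428173516,77.5903244596168],[-73.6038267376363,72.1368036356376],[-82.2649321088809,64.5240721186448],[-88.8670848019261,55.0695958487981],[-93.1817433754819,44.3696465839757],[-95.3844637885325,33.0367611676645],[-95.9490208712422,21.4983368308555],[-95.5128041239195,9.94937230286642],[-104.339057567103,4.46678901695845],[-115.716937478591,2.43156242102418],[-127.035791172906,0.102058826550308],[-133.117026520242,-5.4375196514708],[-121.894665797808,-8.05923963854296],[-110.422939368516,-9.47047987564442],[-98.9816199141809,-11.0787222097384],[-93.9036909650338,-19.6224812597214],[-93.4028441443402,-31.170060367812],[-92.3066218889767,-42.6737527343971],[-90.0383562407694,-53.9999020484959],[-86.1326920547803,-64.864436516737],[-80.3024834527262,-74.8227623027233],[-72.518954164492,-83.3365913985815],[-63.053988118207,-89.9301557957102],[-52.4015342240551,-94.3646131560772],[-41.0975683331058,-96.7070397662848],[-29.5615126270303,-97.2727252024444],[-18.030213276473,-96.5350328249737],[-6.56677286411896,-95.0593385119556],[4.87483329608923,-93.4180264911608],[16.2859062042344,-92.6501057464452],[22.4824206323915,-102.260126099049],[27.320267363168,-112.757631056041],[32.3676996217907,-123.154765529577],[38.6395770063473,-132.819324595502],[42.6398924631713,-125.619323023686],[41.4609954252938,-114.124740119881],[39.7721751998151,-102.690093333469],[38.9450887539439,-91.1944856401237],[48.4967303317916,-86.1665097893197],[59.1326182514823,-81.6782844396423],[68.699467129484,-75.2297659663743],[76.6186414066589,-66.8443454085663],[82.4734874707064,-56.9047560887349],[86.205022276763,-45.9824340891468],[88.1379651027018,-34.5953228623188],[88.9033401678453,-23.0641387526706],[89.3571702705424,-11.5144261415963]],"stroke_meta":[["freehand",0]]}
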